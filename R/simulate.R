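#' Simulate a multi-tissue junction/RBP panel with a planted regulator
#'
#' Emulates, at reduced scale, a GTEx-like panel: `n_tissues` tissues with
#' `samples_per_tissue` samples each, a target gene expressed in
#' `expressing_tissue_count` tissues, two junctions competing for one shared
#' donor site (inclusion vs exclusion of an alternative terminal exon), and a
#' panel of RBPs of which one — the planted regulator — drives inclusion.
#'
#' Per sample: each RBP's log-expression is drawn around a lognormal tissue
#' mean (tissue means `Normal(log 100, 0.7)`, within-tissue spread 0.5); the
#' true inclusion fraction is `plogis(intercept + slope * z)` where `z` is
#' the regulator's standardized log-expression (a negative slope is a
#' PTBP1-like repressor); the junction total is negative binomial
#' (`mu = junction_total_mean`, overdispersion `dispersion`, i.e.
#' `size = 1/dispersion`) in expressing tissues and near zero elsewhere, and
#' the two junction counts are binomially split by the true inclusion.
#'
#' @param n_tissues Number of tissues (default 54).
#' @param samples_per_tissue Samples per tissue (default 30).
#' @param n_rbps Number of RBPs in the panel (default 50).
#' @param expressing_tissue_count Tissues expressing the target gene
#'   (default 10).
#' @param regulator_index Which RBP is the planted regulator (default 1).
#' @param slope Logistic slope `b` linking standardized regulator expression
#'   to inclusion; 0 plants no regulator (default -1.5, a repressor).
#' @param intercept Logistic intercept `a` (default -1, baseline inclusion
#'   about 27%).
#' @param junction_total_mean Mean junction-event coverage in expressing
#'   tissues (default 200 reads).
#' @param dispersion Negative-binomial dispersion of the junction total
#'   (default 0.3).
#' @param target_gene Symbol used for the target gene (default `"TP63"`).
#' @param seed Mandatory integer seed; outputs are a pure function of the
#'   arguments.
#' @return A list with `junction_counts` (2 junctions sharing a donor),
#'   `expression` (RBPs plus the target gene), `attributes`
#'   (`sample_id`, `tissue`, `condition`) and `truth` (regulator name, slope,
#'   intercept, per-sample true inclusion, expressing tissues, RBP names).
#' @export
sim_multitissue_panel <- function(n_tissues = 54, samples_per_tissue = 30,
                                  n_rbps = 50, expressing_tissue_count = 10,
                                  regulator_index = 1, slope = -1.5,
                                  intercept = -1, junction_total_mean = 200,
                                  dispersion = 0.3, target_gene = "TP63",
                                  seed) {
  if (missing(seed)) abort("seed is mandatory.", class = "splicescreen_validation_error")
  stopifnot(n_tissues >= 1, samples_per_tissue >= 1, n_rbps >= 1,
    expressing_tissue_count >= 1, expressing_tissue_count <= n_tissues,
    regulator_index >= 1, regulator_index <= n_rbps,
    junction_total_mean > 0, dispersion > 0)
  withr::with_seed(seed, {
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    expressing <- tissues[seq_len(expressing_tissue_count)]
    samples <- as.vector(vapply(tissues, function(t)
      paste0(t, "_s", sprintf("%02d", seq_len(samples_per_tissue))),
      character(samples_per_tissue)))
    tissue_of <- rep(tissues, each = samples_per_tissue)
    n_s <- length(samples)

    rbps <- sprintf("RBP%03d", seq_len(n_rbps))
    tissue_mu <- matrix(rnorm(n_rbps * n_tissues, log(100), 0.7),
      nrow = n_rbps, dimnames = list(rbps, tissues))
    log_expr <- tissue_mu[, tissue_of, drop = FALSE] +
      matrix(rnorm(n_rbps * n_s, 0, 0.5), nrow = n_rbps)
    expr <- exp(log_expr)
    colnames(expr) <- samples

    regulator <- rbps[regulator_index]
    z <- as.numeric(scale(log_expr[regulator_index, ]))
    inclusion <- plogis(intercept + slope * z)

    is_expr <- tissue_of %in% expressing
    total <- rnbinom(n_s, size = 1 / dispersion,
      mu = ifelse(is_expr, junction_total_mean, 2))
    inc <- rbinom(n_s, size = total, prob = inclusion)
    exc <- total - inc

    target_expr <- exp(ifelse(is_expr, rnorm(n_s, log(500), 0.4),
      rnorm(n_s, log(2), 0.4)))

    junction_counts <- dplyr::bind_cols(
      tibble(
        junction_id = c("chr3:189500001-189520000", "chr3:189500001-189560000"),
        gene = target_gene
      ),
      as_tibble(rbind(inc, exc), .name_repair = ~samples)
    )
    junction_counts <- validate_junction_counts(junction_counts)

    expression <- dplyr::bind_cols(
      tibble(gene = c(rbps, target_gene)),
      as_tibble(rbind(expr, target_expr), .name_repair = ~samples)
    )
    expression <- validate_expression(expression)

    attributes_tbl <- tibble(sample_id = samples, tissue = tissue_of,
      condition = NA_character_)

    list(
      junction_counts = junction_counts,
      expression = expression,
      attributes = attributes_tbl,
      truth = list(
        regulator = regulator, slope = slope, intercept = intercept,
        inclusion = tibble(sample_id = samples, true_inclusion = inclusion),
        expressing_tissues = expressing, rbps = rbps,
        inclusion_junction = "chr3:189500001-189520000",
        exclusion_junction = "chr3:189500001-189560000",
        target_gene = target_gene
      )
    )
  })
}

#' Simulate a tumor cohort with PSI-linked survival and planted DEGs
#'
#' Emulates, at reduced scale, a tumor cohort in which inclusion of an
#' alternative terminal exon stratifies outcome. Each patient's PSI is drawn
#' from a two-component beta mixture (low/high inclusion); the group label is
#' whatever side of `threshold_true` the realized PSI falls on. Survival is
#' exponential with hazard `baseline_hazard * hazard_ratio^(group == high)`,
#' censored by an independent uniform time calibrated (via the mixture's
#' analytic censoring probability) to the requested censoring rate. The first
#' `n_deg` genes are shifted up by `deg_log2fc` log2-units in high-PSI
#' patients (lognormal noise, sdlog 0.5) and carry an `"unfavorable"`
#' prognostic-marker label (high inclusion is the poor-survival group).
#'
#' @param n_patients Cohort size (default 100).
#' @param psi_shape_low,psi_shape_high Beta shape pairs for the low- and
#'   high-inclusion mixture components; defaults `c(1.5, 60)` (mean about
#'   2.4%, the weak terminal-exon inclusion typical of tumors) and
#'   `c(5, 45)` (mean 10%).
#' @param prob_high Mixture weight of the high component (default 0.5).
#' @param threshold_true Planted PSI threshold in percent (default 4.07).
#' @param hazard_ratio Hazard ratio of high vs low group (default 3).
#' @param baseline_hazard Low-group hazard per day; the default gives a
#'   low-group median survival of 2319 days.
#' @param censoring_rate Target fraction censored (default 0.3).
#' @param n_genes,n_deg Total genes and planted differential genes
#'   (defaults 500 and 50).
#' @param deg_log2fc Planted log2 fold change (default 1).
#' @param seed Mandatory integer seed.
#' @return A list with `clinical` (`patient_id`, `time_days`, `event`),
#'   `psi` (`patient_id`, `event_id`, `psi`), `expression` (genes x
#'   patients), `markers` (planted prognostic labels) and `truth` (group
#'   labels, DEG names, threshold, hazard ratio).
#' @export
sim_cohort <- function(n_patients = 100, psi_shape_low = c(1.5, 60),
                       psi_shape_high = c(5, 45), prob_high = 0.5,
                       threshold_true = 4.07, hazard_ratio = 3,
                       baseline_hazard = log(2) / 2319, censoring_rate = 0.3,
                       n_genes = 500, n_deg = 50, deg_log2fc = 1, seed) {
  if (missing(seed)) abort("seed is mandatory.", class = "splicescreen_validation_error")
  stopifnot(n_patients >= 4, hazard_ratio > 0, baseline_hazard > 0,
    censoring_rate >= 0, censoring_rate < 1, n_genes >= 1,
    n_deg >= 0, n_deg <= n_genes)
  withr::with_seed(seed, {
    patients <- sprintf("patient%03d", seq_len(n_patients))
    comp <- rbinom(n_patients, 1, prob_high)
    psi <- 100 * ifelse(comp == 1,
      rbeta(n_patients, psi_shape_high[1], psi_shape_high[2]),
      rbeta(n_patients, psi_shape_low[1], psi_shape_low[2]))
    group <- ifelse(psi >= threshold_true, "high", "low")
    if (length(unique(group)) < 2) {
      abort("Degenerate mixture: all patients fall in one PSI group.",
        class = "splicescreen_validation_error")
    }
    rate <- baseline_hazard * hazard_ratio^(group == "high")
    t_event <- rexp(n_patients, rate)
    if (censoring_rate > 0) {
      # C ~ U(0, cmax); P(C < T) = mean_i (1 - exp(-r_i * cmax)) / (r_i * cmax)
      p_cens <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax))
      cmax <- uniroot(function(cm) p_cens(cm) - censoring_rate,
        lower = 1e-6, upper = 1e9, tol = 1e-8)$root
      c_time <- runif(n_patients, 0, cmax)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    } else {
      cmax <- NA_real_
      time <- t_event
      event <- rep(1L, n_patients)
    }

    genes <- sprintf("GENE%04d", seq_len(n_genes))
    deg_genes <- genes[seq_len(n_deg)]
    base_mu <- runif(n_genes, log(50), log(500))
    shift <- matrix(0, n_genes, n_patients)
    if (n_deg > 0) {
      shift[seq_len(n_deg), group == "high"] <- deg_log2fc * log(2)
    }
    expr <- exp(base_mu + shift + matrix(rnorm(n_genes * n_patients, 0, 0.5),
      n_genes, n_patients))
    colnames(expr) <- patients
    expression <- dplyr::bind_cols(tibble(gene = genes),
      as_tibble(expr, .name_repair = ~patients))
    expression <- validate_expression(expression)

    markers <- if (n_deg > 0) {
      tibble(gene = deg_genes, prognosis = "unfavorable")
    } else {
      tibble(gene = character(0), prognosis = character(0))
    }

    list(
      clinical = tibble(patient_id = patients, time_days = time, event = event),
      psi = tibble(patient_id = patients, event_id = "terminal_exon_inclusion",
        psi = psi),
      expression = expression,
      markers = markers,
      truth = list(
        group = tibble(patient_id = patients, stratum = group),
        deg_genes = deg_genes, threshold_true = threshold_true,
        hazard_ratio = hazard_ratio, baseline_hazard = baseline_hazard,
        censoring_max = cmax
      )
    )
  })
}

#' Simulate an EMSA titration curve with known Kd
#'
#' Bound fractions are the single-site isotherm at the given concentrations
#' plus Gaussian noise, clipped to `[0, 1]` (as gel quantification would be).
#'
#' @param kd True dissociation constant, nmol/L (> 0).
#' @param concs Concentration ladder, nmol/L; default two-fold ladder
#'   12.5-1600.
#' @param noise_sd Gaussian noise SD on the bound fraction (default 0.05).
#' @param n_replicates Replicate curves (default 4).
#' @param probe Probe name recorded in the output.
#' @param seed Mandatory integer seed.
#' @return Tibble (`probe`, `replicate`, `conc`, `bound_frac`).
#' @export
sim_titration <- function(kd, concs = 12.5 * 2^(0:7), noise_sd = 0.05,
                          n_replicates = 4, probe = "probe1", seed) {
  if (missing(seed)) abort("seed is mandatory.", class = "splicescreen_validation_error")
  if (kd <= 0) abort("kd must be positive.", class = "splicescreen_validation_error")
  if (length(concs) == 0) abort("Empty concentration ladder.",
    class = "splicescreen_validation_error")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      f <- isotherm(concs, kd) + rnorm(length(concs), 0, noise_sd)
      tibble(probe = probe, replicate = r, conc = concs,
        bound_frac = pmin(pmax(f, 0), 1))
    })
  })
}
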