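#' Configuration for a synthetic matched case-control cohort
#'
#' Describes a targeted-metabolomics acquisition of matched delirium (DEL)
#' and control (CNT) pairs sampled at two timepoints (PREOP, POD2), batched
#' over several instrument runs with interleaved pooled-QC injections,
#' conditioning samples and blanks. Defaults emulate a 52-pair, 6-run,
#' 315-metabolite design (208 study samples) with roughly 3% missingness.
#'
#' @param n_pairs number of matched DEL/CNT pairs (each contributes 4 study
#'   samples: two subjects times two timepoints).
#' @param n_metabolites total measured channels, including internal standards.
#' @param n_internal_standards spiked internal-standard channels (no
#'   biological signal; they carry loading and drift only).
#' @param n_runs number of instrument runs.
#' @param pairs_per_full_run pairs per full run; the final run takes the
#'   remainder and is "abridged".
#' @param qc_per_run pooled-QC injections per full run; the abridged run
#'   scales this proportionally (floor, minimum 3).
#' @param blanks_per_run,conditioning_per_run blank and conditioning
#'   injections per run (conditioning always opens a run).
#' @param effect_metabolites named list mapping metabolite ids to a named
#'   numeric vector of true log2 DEL/CNT effects per timepoint, e.g.
#'   `list(met_001 = c(PREOP = 0, POD2 = 1))`. Use [spike_effects()] to
#'   build one.
#' @param between_subject_sd biological between-subject SD on the log2 scale.
#' @param within_pair_correlation correlation of paired DEL/CNT subjects'
#'   biological levels (matching on age/sex/comorbidity induces it).
#' @param technical_cv technical coefficient of variation (e.g. 0.05 = 5%);
#'   sets the pooled-QC replicate spread.
#' @param loading_sd per-sample loading-factor SD in log2 units; applied
#'   multiplicatively to every channel including internal standards (the
#'   identifying assumption of internal-standard normalization).
#' @param drift list with `amplitude` (log2 units, peak-to-trough scale) and
#'   `shape` (one of `"linear"`, `"exponential-decay"`, `"spline-knots"`)
#'   describing the per-run injection-order drift curve.
#' @param mnar_quantile intensity quantile below which left-censoring
#'   (missing-not-at-random) ramps in.
#' @param mcar_rate completely-at-random missingness rate.
#' @param seed integer seed; expanded into per-stage substreams.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_pairs = 52L,
                          n_metabolites = 315L,
                          n_internal_standards = 3L,
                          n_runs = 6L,
                          pairs_per_full_run = 10L,
                          qc_per_run = 13L,
                          blanks_per_run = 4L,
                          conditioning_per_run = 3L,
                          effect_metabolites = list(),
                          between_subject_sd = 0.5,
                          within_pair_correlation = 0.6,
                          technical_cv = 0.05,
                          loading_sd = 0.2,
                          drift = list(amplitude = 0.3, shape = "exponential-decay"),
                          mnar_quantile = 0.04,
                          mcar_rate = 0.01,
                          seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    n_metabolites = as.integer(n_metabolites),
    n_internal_standards = as.integer(n_internal_standards),
    n_runs = as.integer(n_runs),
    pairs_per_full_run = as.integer(pairs_per_full_run),
    qc_per_run = as.integer(qc_per_run),
    blanks_per_run = as.integer(blanks_per_run),
    conditioning_per_run = as.integer(conditioning_per_run),
    effect_metabolites = effect_metabolites,
    between_subject_sd = between_subject_sd,
    within_pair_correlation = within_pair_correlation,
    technical_cv = technical_cv,
    loading_sd = loading_sd,
    drift = drift,
    mnar_quantile = mnar_quantile,
    mcar_rate = mcar_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_pairs > cfg$n_runs * cfg$pairs_per_full_run) {
    stop("infeasible packing: n_pairs exceeds n_runs * pairs_per_full_run", call. = FALSE)
  }
  if (cfg$within_pair_correlation < 0 || cfg$within_pair_correlation >= 1) {
    stop("within_pair_correlation must be in [0, 1)", call. = FALSE)
  }
  if (cfg$mnar_quantile < 0 || cfg$mnar_quantile >= 1 ||
      cfg$mcar_rate < 0 || cfg$mcar_rate >= 1 ||
      cfg$mnar_quantile + cfg$mcar_rate >= 0.5) {
    stop("mnar_quantile + mcar_rate must keep overall missingness below 0.5", call. = FALSE)
  }
  if (!cfg$drift$shape %in% c("linear", "exponential-decay", "spline-knots")) {
    stop("unknown drift shape: ", cfg$drift$shape, call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Spike true effects into a cohort configuration
#'
#' @param metabolite_ids ids to spike (e.g. `sprintf("met_%03d", 1:20)`).
#' @param log2fc signed log2 fold change (DEL over CNT), recycled.
#' @param timepoint `"PREOP"`, `"POD2"` or `"both"`.
#' @return a list suitable for `cohort_config(effect_metabolites = )`.
#' @export
spike_effects <- function(metabolite_ids, log2fc, timepoint = "POD2") {
  log2fc <- rep_len(log2fc, length(metabolite_ids))
  stats::setNames(lapply(seq_along(metabolite_ids), function(i) {
    c(PREOP = if (timepoint %in% c("PREOP", "both")) log2fc[i] else 0,
      POD2 = if (timepoint %in% c("POD2", "both")) log2fc[i] else 0)
  }), metabolite_ids)
}

# deterministic per-stage substream of the global seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 20011L + h %% 20011L
}

# snapshot the caller's RNG state; returns a restorer
snapshot_rng <- function() {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  function() {
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  restore <- snapshot_rng()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Build the acquisition layout for a cohort
#'
#' Each run opens with conditioning injections; blanks sit at fixed evenly
#' spread slots; pooled QCs are interleaved evenly through the analytic
#' sequence; the four study samples of a pair always share a run.
#' Injection order is consecutive within each run.
#'
#' @param config a [cohort_config()].
#' @return tibble of sample metadata in acquisition order.
#' @export
make_run_layout <- function(config) {
  cfg <- config
  pair_ids <- sprintf("P%02d", seq_len(cfg$n_pairs))
  run_of_pair <- ceiling(seq_len(cfg$n_pairs) / cfg$pairs_per_full_run)
  rows <- vector("list", cfg$n_runs)
  n_runs_used <- max(run_of_pair)
  for (r in seq_len(n_runs_used)) {
    pr <- pair_ids[run_of_pair == r]
    qc_n <- if (length(pr) < cfg$pairs_per_full_run) {
      max(3L, as.integer(floor(cfg$qc_per_run * length(pr) / cfg$pairs_per_full_run)))
    } else cfg$qc_per_run
    study <- tidyr::expand_grid(pair_id = pr,
                                timepoint = TIMEPOINT_LEVELS,
                                group = c("DEL", "CNT"))
    n_analytic <- nrow(study) + qc_n + cfg$blanks_per_run
    slots <- rep(NA_character_, n_analytic)
    blank_pos <- unique(round(seq(1, n_analytic, length.out = cfg$blanks_per_run)))
    slots[blank_pos] <- "BLANK"
    open <- which(is.na(slots))
    qc_pos <- open[unique(round(seq(1, length(open), length.out = qc_n)))]
    slots[qc_pos] <- "QC"
    slots[is.na(slots)] <- "STUDY"
    out <- tibble::tibble(
      group = c(rep("CONDITIONING", cfg$conditioning_per_run), slots),
      run_id = r
    )
    si <- 0L
    qi <- 0L
    bi <- 0L
    ci <- 0L
    meta <- lapply(seq_len(nrow(out)), function(i) {
      g <- out$group[i]
      if (g == "STUDY") {
        si <<- si + 1L
        st <- study[si, ]
        tibble::tibble(
          sample_id = sprintf("%s_%s_%s", st$pair_id, st$group, st$timepoint),
          subject_id = sprintf("%s_%s", st$pair_id, substr(st$group, 1, 1)),
          pair_id = st$pair_id, group = st$group, timepoint = st$timepoint
        )
      } else {
        idx <- switch(g,
          QC = {qi <<- qi + 1L; qi},
          BLANK = {bi <<- bi + 1L; bi},
          CONDITIONING = {ci <<- ci + 1L; ci}
        )
        tibble::tibble(
          sample_id = sprintf("R%d_%s_%02d", r, g, idx),
          subject_id = NA_character_, pair_id = NA_character_,
          group = g, timepoint = NA_character_
        )
      }
    })
    rows[[r]] <- dplyr::bind_cols(dplyr::bind_rows(meta),
                                  run_id = out$run_id) |>
      dplyr::mutate(injection_order = dplyr::row_number())
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("sample_id", "subject_id", "pair_id", "group", "timepoint",
                  "run_id", "injection_order")
}

drift_shape <- function(u, shape, knots = NULL) {
  raw <- switch(shape,
    "linear" = u,
    "exponential-decay" = exp(-3 * u),
    "spline-knots" = {
      xs <- seq(0, 1, length.out = length(knots))
      stats::spline(xs, knots, xout = u)$y
    }
  )
  raw - mean(raw)
}

#' Generate a synthetic cohort with its ground-truth ledger
#'
#' Biological abundances are log-normal with a pair-shared random effect
#' (inducing the within-pair correlation of the matched design); DEL samples
#' are shifted by the configured log2 effects. A per-sample loading factor
#' multiplies every channel including the internal standards; a smooth
#' per-run drift curve multiplies each channel with metabolite-specific
#' sensitivity; pooled QCs are technical replicates of a fixed pool (no
#' biological variance). Missingness is then applied: probabilistic left
#' censoring below the configured intensity quantile (MNAR, ramping to
#' certainty at the metabolite minimum) plus uniform MCAR dropout.
#' Internal standards are spiked at high concentration and never censored.
#'
#' @param config a [cohort_config()].
#' @return list with `cohort` (a [metab_cohort()]) and `truth` (ledger:
#'   effects, drift curves, loading factors, missingness mechanism, seed).
#' @export
generate_cohort <- function(config) {
  cfg <- config
  restore_rng <- snapshot_rng()
  on.exit(restore_rng(), add = TRUE)
  samples <- make_run_layout(cfg)
  n_s <- nrow(samples)
  n_m <- cfg$n_metabolites
  n_is <- cfg$n_internal_standards
  met_ids <- c(sprintf("met_%03d", seq_len(n_m - n_is)),
               sprintf("IS_%d", seq_len(n_is)))
  is_std <- c(rep(FALSE, n_m - n_is), rep(TRUE, n_is))
  metabolites <- tibble::tibble(
    metabolite_id = met_ids,
    display_name = met_ids,
    is_internal_standard = is_std
  )

  set.seed(stage_seed(cfg$seed, "base"))
  mu <- stats::runif(n_m, 10, 20)          # log2 instrument units
  mu[is_std] <- stats::runif(n_is, 18, 20) # standards spiked high
  sens <- stats::runif(n_m, 0.5, 1.5)      # drift sensitivity per metabolite

  # biological layer: pair-shared + individual effects (log2)
  rho <- cfg$within_pair_correlation
  sd_pair <- cfg$between_subject_sd * sqrt(rho)
  sd_ind <- cfg$between_subject_sd * sqrt(1 - rho)
  pair_ids <- sprintf("P%02d", seq_len(cfg$n_pairs))
  set.seed(stage_seed(cfg$seed, "biology"))
  pair_eff <- matrix(stats::rnorm(cfg$n_pairs * n_m, 0, sd_pair),
                     cfg$n_pairs, n_m, dimnames = list(pair_ids, met_ids))
  subj_ids <- as.vector(outer(pair_ids, c("D", "C"), paste, sep = "_"))
  subj_eff <- matrix(stats::rnorm(length(subj_ids) * n_m, 0, sd_ind),
                     length(subj_ids), n_m, dimnames = list(subj_ids, met_ids))
  pair_eff[, is_std] <- 0
  subj_eff[, is_std] <- 0

  # true effects (log2 DEL/CNT per timepoint)
  eff <- matrix(0, n_m, 2, dimnames = list(met_ids, TIMEPOINT_LEVELS))
  for (id in names(cfg$effect_metabolites)) {
    if (!id %in% met_ids) stop("effect metabolite not in panel: ", id, call. = FALSE)
    e <- cfg$effect_metabolites[[id]]
    eff[id, names(e)] <- e
  }
  eff[is_std, ] <- 0

  set.seed(stage_seed(cfg$seed, "loading"))
  loading <- stats::rnorm(n_s, 0, cfg$loading_sd)
  names(loading) <- samples$sample_id

  set.seed(stage_seed(cfg$seed, "drift"))
  runs <- sort(unique(samples$run_id))
  drift_curves <- lapply(runs, function(r) {
    list(amplitude = cfg$drift$amplitude, shape = cfg$drift$shape,
         knots = if (cfg$drift$shape == "spline-knots") stats::rnorm(5) else NULL)
  })
  names(drift_curves) <- as.character(runs)

  set.seed(stage_seed(cfg$seed, "noise"))
  sd_tech <- cfg$technical_cv / log(2)  # CV on natural scale ~ sd of log2 * ln2
  log2v <- matrix(rep(mu, each = n_s), n_s, n_m,
                  dimnames = list(samples$sample_id, met_ids))
  grp <- samples$group
  for (i in seq_len(n_s)) {
    if (grp[i] %in% c("DEL", "CNT")) {
      p <- samples$pair_id[i]
      subj <- sprintf("%s_%s", p, substr(grp[i], 1, 1))
      log2v[i, ] <- log2v[i, ] + pair_eff[p, ] + subj_eff[subj, ]
      if (grp[i] == "DEL") log2v[i, ] <- log2v[i, ] + eff[, samples$timepoint[i]]
    } else if (grp[i] == "BLANK") {
      log2v[i, ] <- log2v[i, ] - 9   # near-background carryover level
    }
    # QC and CONDITIONING stay at the pooled mean (no biological variance)
  }
  # per-run drift, metabolite-specific sensitivity
  for (r in runs) {
    sel <- samples$run_id == r
    ord <- samples$injection_order[sel]
    u <- (ord - min(ord)) / max(1L, diff(range(ord)))
    dc <- drift_curves[[as.character(r)]]
    shp <- drift_shape(u, dc$shape, dc$knots)
    log2v[sel, ] <- log2v[sel, ] + (shp * dc$amplitude) %o% sens
  }
  log2v <- log2v + loading  # recycles down columns: per-sample factor
  log2v <- log2v + matrix(stats::rnorm(n_s * n_m, 0, sd_tech), n_s, n_m)
  values <- 2^log2v

  # missingness: MNAR left-censoring ramp then MCAR; standards exempt
  set.seed(stage_seed(cfg$seed, "missing"))
  mechanism <- matrix("observed", n_s, n_m,
                      dimnames = list(samples$sample_id, met_ids))
  cens_rows <- grp %in% c("DEL", "CNT", "QC")
  if (cfg$mnar_quantile > 0) {
    for (j in which(!is_std)) {
      x <- values[cens_rows, j]
      q <- stats::quantile(x, cfg$mnar_quantile, names = FALSE)
      lo <- min(x)
      if (q > lo) {
        pmiss <- pmax(0, pmin(1, (q - x) / (q - lo)))
        hit <- stats::runif(length(x)) < pmiss
        mechanism[cens_rows, j][hit] <- "mnar"
      }
    }
  }
  if (cfg$mcar_rate > 0) {
    mcar <- matrix(stats::runif(n_s * n_m) < cfg$mcar_rate, n_s, n_m)
    mcar[!cens_rows, ] <- FALSE
    mcar[, is_std] <- FALSE
    mechanism[mcar & mechanism == "observed"] <- "mcar"
  }
  values[mechanism != "observed"] <- NA_real_

  cohort <- metab_cohort(values, samples, metabolites)
  truth <- structure(list(
    effects = tibble::as_tibble(as.data.frame(eff)) |>
      dplyr::mutate(metabolite_id = met_ids, .before = 1L) |>
      tidyr::pivot_longer(-"metabolite_id", names_to = "timepoint",
                          values_to = "log2fc"),
    drift_curves = drift_curves,
    drift_sensitivity = stats::setNames(sens, met_ids),
    loading = loading,
    mechanism = mechanism,
    base_log2_mean = stats::setNames(mu, met_ids),
    seed = cfg$seed,
    config = cfg
  ), class = "truth_ledger")
  list(cohort = cohort, truth = truth)
}

#' Score detections against the synthetic ground truth
#'
#' @param results a [univariate_table()] tibble with `consensus` (and
#'   optionally `b_log2`) columns.
#' @param truth the `truth` ledger from [generate_cohort()].
#' @param timepoint which timepoint's spiked effects to score against.
#' @return one-row tibble: `sensitivity` (spiked metabolites detected),
#'   `fdr` (detections that were not spiked; 0 when nothing detected),
#'   `fc_bias` (mean estimated-minus-true log2 FC over spiked), `n_spiked`,
#'   `n_detected`.
#' @export
truth_eval <- function(results, truth, timepoint = "POD2") {
  spiked <- truth$effects |>
    dplyr::filter(.data$timepoint == !!timepoint, .data$log2fc != 0)
  unknown <- setdiff(results$metabolite_id,
                     unique(truth$effects$metabolite_id))
  if (length(unknown)) {
    stop("results contain metabolites absent from the ledger: ",
         unknown[1], call. = FALSE)
  }
  det <- results$metabolite_id[results$consensus]
  hits <- intersect(det, spiked$metabolite_id)
  sens <- if (nrow(spiked)) length(hits) / nrow(spiked) else NA_real_
  fdr <- if (length(det)) length(setdiff(det, spiked$metabolite_id)) / length(det) else 0
  fc_bias <- NA_real_
  if ("b_log2" %in% names(results) && nrow(spiked)) {
    est <- results$b_log2[match(spiked$metabolite_id, results$metabolite_id)]
    fc_bias <- mean(est - spiked$log2fc, na.rm = TRUE)
  }
  tibble::tibble(sensitivity = sens, fdr = fdr, fc_bias = fc_bias,
                 n_spiked = nrow(spiked), n_detected = length(det))
}
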