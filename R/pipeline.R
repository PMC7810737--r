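#' Pipeline configuration
#'
#' Collects every stage's parameters for [run_pipeline()]: simulate (or read
#' an existing matrix), preprocess, univariate per timepoint, multivariate,
#' and optional pathway enrichment.
#'
#' @param cohort a [cohort_config()] to simulate, or a path to a wide CSV
#'   matrix to read.
#' @param out_dir output directory for artifacts (`NULL` for none).
#' @param timepoints which timepoints to analyse.
#' @param level named per-timepoint consensus level: the PREOP contrast
#'   conventionally uses nominal p (few metabolites survive BH
#'   preoperatively), POD2 the BH level.
#' @param alpha,min_tests consensus parameters.
#' @param robust_iters split-robustness iterations (0 disables the stage).
#' @param n_ortho named per-timepoint orthogonal component counts.
#' @param folds,n_perm cross-validation folds and permutation count.
#' @param vip_threshold VIP cutoff defining the SVM panel.
#' @param drift_method,k preprocessing options (see [preprocess_cohort()]).
#' @param pathway_library optional `pathway_library` (or GMT path) enabling
#'   the enrichment stage.
#' @param universe `"library"` or a compound-id vector.
#' @param seed global seed; stages derive substreams from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            out_dir = NULL,
                            timepoints = c("PREOP", "POD2"),
                            level = c(PREOP = "nominal", POD2 = "BH"),
                            alpha = 0.05, min_tests = 2L,
                            robust_iters = 0L,
                            n_ortho = c(PREOP = 1L, POD2 = 2L),
                            folds = 7L, n_perm = 1000L,
                            vip_threshold = 2.0,
                            drift_method = "rf", k = 10L,
                            pathway_library = NULL,
                            universe = "library",
                            seed = 17L) {
  if (is.character(pathway_library)) {
    if (!file.exists(pathway_library)) {
      stop("pathway library file not found: ", pathway_library, call. = FALSE)
    }
    pathway_library <- read_pathway_library(pathway_library)
  }
  structure(list(
    cohort = cohort, out_dir = out_dir, timepoints = timepoints,
    level = level, alpha = alpha, min_tests = as.integer(min_tests),
    robust_iters = as.integer(robust_iters), n_ortho = n_ortho,
    folds = as.integer(folds), n_perm = as.integer(n_perm),
    vip_threshold = vip_threshold, drift_method = drift_method,
    k = as.integer(k), pathway_library = pathway_library,
    universe = universe, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or read), preprocess, univariate consensus testing with
#' optional split-robustness, OPLS-DA with validation and VIP-panel SVM,
#' and optional pathway enrichment — per timepoint, under one global seed
#' with per-stage substreams. Artifacts (tables, manifest with md5
#' checksums) are written when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list: `cohort`, `truth` (when simulated),
#'   `preprocess` (mask + RSD audits), `univariate`, `robustness`,
#'   `multivariate` (per-timepoint model, Q2, CV-ANOVA, permutation, panel),
#'   `enrichment`, `overlap`, `manifest`, `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  truth <- NULL
  if (inherits(cfg$cohort, "cohort_config")) {
    sim_cfg <- cfg$cohort
    sim_cfg$seed <- stage_seed(cfg$seed, "simulate")
    gen <- generate_cohort(sim_cfg)
    cohort <- gen$cohort
    truth <- gen$truth
  } else if (is.character(cfg$cohort)) {
    cohort <- read_intensity_matrix(cfg$cohort, "wide")
  } else {
    cohort <- cfg$cohort
  }
  prep <- preprocess_cohort(cohort, drift_method = cfg$drift_method,
                            k = cfg$k, seed = stage_seed(cfg$seed, "preprocess"))
  pc <- prep$cohort
  study <- which(is_study_sample(pc))
  univ <- list(); robust <- list(); multi <- list(); enr <- list()
  for (tp in cfg$timepoints) {
    lev <- unname(cfg$level[[tp]] %||% "BH")
    univ[[tp]] <- univariate_table(pc, tp, level = lev,
                                   alpha = cfg$alpha, min_tests = cfg$min_tests)
    if (cfg$robust_iters > 0L) {
      rb <- split_robustness(pc, tp, n_iter = cfg$robust_iters,
                             level = lev, alpha = cfg$alpha,
                             min_tests = cfg$min_tests,
                             seed = stage_seed(cfg$seed, paste0("robust-", tp)))
      robust[[tp]] <- rb
      univ[[tp]] <- dplyr::left_join(univ[[tp]], rb, by = "metabolite_id")
    }
    tp_rows <- study[pc$samples$timepoint[study] == tp]
    sub <- cohort_subset(pc, samples = tp_rows)
    X <- log2(cohort_values(sub))
    y <- factor(cohort_samples(sub)$group, levels = c("CNT", "DEL"))
    pairs <- cohort_samples(sub)$pair_id
    screen <- pca_outlier_screen(X)
    keep <- !screen$outlier
    Xk <- X[keep, , drop = FALSE]
    yk <- droplevels(y[keep])
    pk <- pairs[keep]
    n_o <- unname(cfg$n_ortho[[tp]] %||% 1L)
    model <- fit_opls_da(Xk, yk, n_ortho = n_o)
    q2 <- q2_cross_validate(Xk, yk, n_o, cfg$folds, pk,
                            seed = stage_seed(cfg$seed, paste0("q2-", tp)))
    attr(model, "Q2") <- as.numeric(q2)
    cva <- cv_anova(Xk, yk, n_o, cfg$folds, pk,
                    seed = stage_seed(cfg$seed, paste0("cva-", tp)))
    perm <- if (cfg$n_perm > 0L) {
      permutation_validate(Xk, yk, n_o, cfg$n_perm, cfg$folds, pk,
                           seed = stage_seed(cfg$seed, paste0("perm-", tp)))
    }
    panel <- names(model$VIP)[model$VIP > cfg$vip_threshold]
    svm <- if (length(panel) >= 1L) {
      svm_panel_auc(Xk, yk, panel, pairs = pk,
                    seed = stage_seed(cfg$seed, paste0("svm-", tp)))
    }
    # univariate table carries the VIP column of the timepoint's model
    univ[[tp]]$VIP <- unname(model$VIP[univ[[tp]]$metabolite_id])
    multi[[tp]] <- list(outliers = screen$sample[screen$outlier],
                        model = model, Q2 = as.numeric(q2),
                        cv_anova = cva, permutation = perm,
                        panel = panel, svm = svm)
    if (!is.null(cfg$pathway_library)) {
      sig <- univ[[tp]]$metabolite_id[univ[[tp]]$consensus]
      enr[[tp]] <- if (length(sig)) {
        enrich_pathways(sig, cfg$pathway_library, cfg$universe)
      }
    }
  }
  overlap <- if (all(c("PREOP", "POD2") %in% names(univ))) {
    compare_timepoints(univ$PREOP, univ$POD2)
  }
  manifest <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tp in names(univ)) {
      d <- file.path(cfg$out_dir, tp)
      write_report_tables(univ[[tp]], d)
      if (!is.null(enr[[tp]])) write_report_tables(enr[[tp]], d)
      write_report_tables(multi[[tp]]$model, d)
    }
    files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- tibble::tibble(
      file = sub(paste0("^", cfg$out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files))
    )
    readr::write_tsv(manifest, file.path(cfg$out_dir, "MANIFEST.tsv"),
                     progress = FALSE)
  }
  structure(list(cohort = cohort, truth = truth, preprocess = prep,
                 univariate = univ, robustness = robust,
                 multivariate = multi, enrichment = enr,
                 overlap = overlap, manifest = manifest, config = cfg),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (tp in names(x$univariate)) {
    u <- x$univariate[[tp]]
    m <- x$multivariate[[tp]]
    cat(sprintf("  %s: %d/%d consensus metabolites; R2Y = %.3f, Q2 = %.3f",
                tp, sum(u$consensus), nrow(u), m$model$R2Y, m$Q2))
    if (!is.null(m$svm)) cat(sprintf("; panel AUC = %.1f%%", m$svm$auc))
    cat("\n")
  }
  invisible(x)
}

#' Overlap of consensus calls between timepoints
#'
#' Intersects the consensus sets of two univariate tables and flags, per
#' shared metabolite, whether the fold-change direction agrees.
#'
#' @param preop,pod2 [univariate_table()] tibbles over the same panel.
#' @return list: `overlap` tibble (metabolite_id, fc_preop, fc_pod2,
#'   sign_agrees), `n_shared`, `n_sign_flipped`.
#' @export
compare_timepoints <- function(preop, pod2) {
  if (!setequal(preop$metabolite_id, pod2$metabolite_id)) {
    stop("tables cover different metabolite panels", call. = FALSE)
  }
  shared <- intersect(preop$metabolite_id[preop$consensus],
                      pod2$metabolite_id[pod2$consensus])
  tab <- tibble::tibble(
    metabolite_id = shared,
    fc_preop = preop$FC[match(shared, preop$metabolite_id)],
    fc_pod2 = pod2$FC[match(shared, pod2$metabolite_id)]
  )
  tab$sign_agrees <- sign(tab$fc_preop) == sign(tab$fc_pod2)
  list(overlap = tab, n_shared = nrow(tab),
       n_sign_flipped = sum(!tab$sign_agrees))
}
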