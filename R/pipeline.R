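#' Experiment configuration
#'
#' Declarative description of a full desk-scale evaluation: which marker
#' panels and prediction models to run, with which annotation grouping,
#' MCMC and bootstrap settings, on a simulated cohort.
#'
#' @param sim a [sim_config()] describing the cohort.
#' @param panels character vector of panel names understood by
#'   [build_panel()] (plus `"MMD"` for the medium-density array subset).
#' @param models character vector from `gblup_c`, `gblup_s`, `mgfblup_c`,
#'   `mgfblup_s`, `bayescpi`, `bayesr`, `bayesrrrc`, `bslmm`.
#' @param grouping annotation model used by MGFBLUP/BayesRR-RC
#'   (`"FAN1"` or `"FAN2"`).
#' @param traits trait columns to evaluate (`NULL` = all simulated traits).
#' @param mcmc an [mcmc_config()] (its seed is re-derived per cell).
#' @param n_boot bootstrap resamples for significance testing.
#' @param h2_eval heritability used in the reliability denominator;
#'   `"true"` uses the realized simulated heritability, `"reml"` the
#'   reference-set REML estimate under the baseline GBLUP model, or a
#'   fixed numeric value.
#' @param seed master seed; per-cell seeds are derived deterministically
#'   from it and the cell's (panel, model) name, so results do not depend
#'   on the order panels or models are listed.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), panels = c("WGS", "FUN1"),
                       models = c("gblup_c", "bayesr"),
                       grouping = "FAN1", traits = NULL,
                       mcmc = mcmc_config(n_iter = 1500, burn_in = 500),
                       n_boot = 2000, h2_eval = "true", seed = 1) {
  known <- c("gblup_c", "gblup_s", "mgfblup_c", "mgfblup_s", "bayescpi",
             "bayesr", "bayesrrrc", "bslmm")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  structure(list(sim = sim, panels = panels, models = models,
                 grouping = grouping, traits = traits, mcmc = mcmc,
                 n_boot = n_boot, h2_eval = h2_eval, seed = seed),
            class = "run_config")
}

# Deterministic small seed from a string, independent of evaluation order.
.cell_seed <- function(master, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.integer(master) * 10007L + h %% 100003L) %% 2147480000L
}

#' Run a full evaluation experiment
#'
#' Simulates a cohort, applies QC, builds the requested marker panels,
#' fits every (panel, model) combination on the reference individuals
#' (born before the cutoff), predicts the target individuals, and reports
#' reliability per trait and cell plus pairwise bootstrap significance per
#' trait. Per-cell seeds are derived from the master seed and the cell
#' name, so report cells are invariant to the order panels and models are
#' listed.
#'
#' @param cfg a [run_config()].
#' @param verbose print per-stage progress lines.
#' @return object of class `gsannot_report`: `reliability` (tibble trait x
#'   panel x model with reliability and dispersion bias), `bootstrap`
#'   (list of `gsannot_boot` per trait), `gebv` (tibble of target GEBVs),
#'   `h2_eval`, `split`, `cfg`.
#' @export
run_experiment <- function(cfg, verbose = TRUE) {
  say <- function(...) if (verbose) message("[gsannot] ", ...)
  t0 <- Sys.time()
  say("simulate: n=", cfg$sim$n_individuals, " M=", cfg$sim$n_markers,
      " seed=", cfg$sim$seed)
  dat <- simulate_dataset(cfg$sim)
  geno <- filter_markers(dat$geno, maf_min = 0.01, hwe_p_min = 0.001)
  say("qc: ", n_markers(geno), "/", n_markers(dat$geno), " markers retained")
  traits <- cfg$traits %||% setdiff(names(dat$pheno), c("sample_id", "birth_date"))
  split <- split_by_date(dat$pheno, cfg$sim$split_cutoff)
  say("split: ", length(split$reference), " reference / ",
      length(split$target), " target")
  panels <- lapply(stats::setNames(cfg$panels, cfg$panels), function(p) {
    build_panel(geno, dat$tracks, p)
  })
  rel_rows <- list()
  gebv_all <- tibble::tibble(sample_id = split$target)
  for (p in cfg$panels) {
    gp <- subset_genotypes(geno, markers = panels[[p]])
    say("panel ", p, ": ", n_markers(gp), " markers")
    need_grm <- any(cfg$models %in% c("gblup_c", "gblup_s", "mgfblup_c",
                                      "mgfblup_s", "bslmm"))
    grm_c <- if (need_grm) compute_grm(gp, "centered") else NULL
    grm_s <- if (any(cfg$models %in% c("gblup_s", "mgfblup_s")))
      compute_grm(gp, "standardized") else NULL
    anno_p <- switch(cfg$grouping,
                     FAN1 = assign_fan1(gp, dat$tracks),
                     FAN2 = assign_fan2(gp, dat$tracks))
    for (mod in cfg$models) {
      key <- paste(p, mod, sep = "|")
      cell_seed <- .cell_seed(cfg$seed, key)
      for (tr in traits) {
        ph_ref <- dat$pheno[dat$pheno$sample_id %in% split$reference,
                            c("sample_id", tr)]
        names(ph_ref)[2] <- "value"
        pred <- .fit_cell(mod, gp, grm_c, grm_s, anno_p, ph_ref, split,
                          cfg, cell_seed)
        col <- paste(p, mod, tr, sep = ".")
        gebv_all[[col]] <- pred$gebv[match(split$target, pred$sample_id)]
        rel_rows[[col]] <- tibble::tibble(trait = tr, panel = p, model = mod)
      }
      say("  fitted ", mod)
    }
  }
  h2v <- lapply(stats::setNames(traits, traits), function(tr) {
    if (identical(cfg$h2_eval, "true")) {
      if (!is.null(dat$truth[[tr]])) dat$truth[[tr]]$true_h2_realized
      else mean(vapply(dat$truth, function(x) x$true_h2_realized, numeric(1)))
    } else if (identical(cfg$h2_eval, "reml")) {
      gref <- subset_grm(compute_grm(geno, "centered"), split$reference)
      ph <- dat$pheno[dat$pheno$sample_id %in% split$reference,
                      c("sample_id", tr)]
      names(ph)[2] <- "value"
      reml_fit(ph, gref)$h2
    } else as.numeric(cfg$h2_eval)
  })
  rel <- purrr::imap_dfr(rel_rows, function(row, col) {
    tr <- row$trait
    yv <- stats::setNames(dat$pheno[[tr]], dat$pheno$sample_id)[split$target]
    g <- gebv_all[[col]]
    dplyr::mutate(row,
                  reliability = reliability(g, yv, h2v[[tr]]),
                  bias = dispersion_bias(g, yv))
  })
  boots <- lapply(stats::setNames(traits, traits), function(tr) {
    cols <- names(gebv_all)[endsWith(names(gebv_all), paste0(".", tr))]
    if (length(cols) < 2) return(NULL)
    tab <- gebv_all[, c("sample_id", cols)]
    names(tab) <- c("sample_id", sub(paste0(".", tr), "", cols, fixed = TRUE))
    yv <- stats::setNames(dat$pheno[[tr]], dat$pheno$sample_id)[split$target]
    bootstrap_compare(tab, yv, h2v[[tr]], n_boot = cfg$n_boot,
                      seed = .cell_seed(cfg$seed, paste0("boot|", tr)))
  })
  say("done in ", round(as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      " s")
  structure(list(reliability = rel, bootstrap = boots, gebv = gebv_all,
                 h2_eval = unlist(h2v), split = split, cfg = cfg),
            class = "gsannot_report")
}

.fit_cell <- function(mod, gp, grm_c, grm_s, anno_p, ph_ref, split, cfg,
                      cell_seed) {
  mc <- cfg$mcmc
  mc$seed <- cell_seed
  if (mod %in% c("gblup_c", "gblup_s", "mgfblup_c", "mgfblup_s")) {
    mode <- if (endsWith(mod, "_s")) "standardized" else "centered"
    grms <- if (startsWith(mod, "mgfblup")) {
      group_grms(gp, anno_p, mode, min_group_size = 2)
    } else {
      list(all = if (mode == "centered") grm_c else grm_s)
    }
    grms_ref <- lapply(grms, subset_grm, samples = intersect(
      ph_ref$sample_id, grms[[1]]$sample_ids))
    vc <- reml_fit(ph_ref, grms_ref)
    blup_predict(ph_ref, grms, vc, split$target)
  } else {
    gref <- subset_genotypes(gp, samples = intersect(gp$sample_ids,
                                                     ph_ref$sample_id))
    gtar <- subset_genotypes(gp, samples = split$target)
    post <- switch(mod,
      bayescpi = suppressWarnings(run_bayes_cpi(ph_ref, gref, cfg = mc)),
      bayesr = suppressWarnings(run_bayes_r(ph_ref, gref, cfg = mc)),
      bayesrrrc = {
        anno_ref <- annotation_map(
          anno_p$assignments[anno_p$assignments$marker_id %in%
                               gref$marker_meta$marker_id, ],
          attr(anno_p, "model_name"), attr(anno_p, "group_labels"))
        suppressWarnings(run_bayes_rr_rc(ph_ref, gref, anno_ref, cfg = mc))
      },
      bslmm = {
        gref_grm <- subset_grm(grm_c, gref$sample_ids)
        run_bslmm(ph_ref, gref, grm = gref_grm, cfg = mc)
      })
    grm_arg <- if (mod == "bslmm") grm_c else NULL
    predict_from_posterior(post, gtar, grm = grm_arg)
  }
}

#' @export
print.gsannot_report <- function(x, ...) {
  cat("<gsannot_report> ", nrow(x$reliability), " cells (",
      length(unique(x$reliability$trait)), " traits x ",
      length(unique(x$reliability$panel)), " panels x ",
      length(unique(x$reliability$model)), " models)\n", sep = "")
  print(dplyr::arrange(x$reliability, dplyr::desc(.data$reliability)), n = 12)
  invisible(x)
}
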