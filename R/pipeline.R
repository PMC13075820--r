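stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> treatment-effect model -> per-treatment
#' variance components -> haplodiploid heritability -> life-history costs,
#' and writes all outputs (CSV tables, JSON results, a markdown report and a
#' run manifest) to `out_dir`. Identical inputs and seed reproduce identical
#' output files.
#'
#' The heritability conversion is attempted for each treatment arm but
#' gated: an arm whose response variance falls below `var_floor` (as in a
#' control arm with almost no mortality) or whose variance-component fit is
#' degenerate reports `"not estimable"` instead of a number.
#'
#' @param config A [sim_config()]; in `"from-files"` mode only used as
#'   fallback metadata and may be `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param mode `"simulate"` (generate data from `config`) or `"from-files"`
#'   (read `survival.csv` / `life_history.csv` from `in_dir`).
#' @param in_dir Input directory for `"from-files"` mode.
#' @param seed Optional integer overriding `config$seed`.
#' @param var_floor Response-variance floor below which heritability is
#'   reported as not estimable.
#' @return Object of class `run_bundle` (invisibly): all fitted objects,
#'   summaries, output paths and the manifest.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(paper_survival_config(seed = 1), out_dir = tempfile())
#' out$heritability$exposed$h2
#' }
run_pipeline <- function(config = paper_survival_config(),
                         out_dir,
                         mode = c("simulate", "from-files"),
                         in_dir = NULL,
                         seed = NULL,
                         var_floor = 1e-6) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(seed) && !is.null(config)) {
    config$seed <- as.integer(seed)
  }

  if (mode == "simulate") {
    check_that(inherits(config, "sim_config"), "`config` required in simulate mode")
    surv <- stage("simulate_survival", simulate_survival_data(config))
    life <- stage("simulate_life_history", simulate_life_history(config))
  } else {
    check_that(!is.null(in_dir), "`in_dir` required in from-files mode")
    tabs <- stage("read_tables", read_tables(in_dir))
    surv <- tabs$survival
    life <- tabs$life_history
  }

  bundle <- list(config = config, mode = mode)
  results <- list()

  if (!is.null(surv)) {
    stage("write_survival", write_tables(list(survival = surv), out_dir))
    bundle$survival <- surv
    bundle$treatment_model <- stage("binomial_mixed", fit_binomial_mixed(surv))
    results$treatment_effect <- list(
      log_odds = bundle$treatment_model$coefficients$estimate[2],
      statistic = bundle$treatment_model$statistic,
      df = bundle$treatment_model$df,
      p_value = bundle$treatment_model$p_value,
      flags = bundle$treatment_model$flags,
      note = bundle$treatment_model$caveat
    )

    bundle$vc <- list()
    bundle$heritability <- list()
    results$survival <- list()
    for (arm in c("exposed", "control")) {
      d <- dplyr::filter(surv, .data$treatment == arm)
      if (nrow(d) == 0) next
      pd <- d$n_dead_day10 / d$n_nymphs
      if (var(pd) < var_floor) {
        bundle$vc[[arm]] <- NULL
        bundle$heritability[[arm]] <- list(h2 = NA_real_, status = "not estimable",
                                           reason = "insufficient variation")
        results$survival[[arm]] <- list(
          mortality = mean(d$n_dead_day10) / mean(d$n_nymphs),
          heritability = "not estimable",
          reason = "insufficient variation"
        )
        next
      }
      fit <- stage(paste0("reml_", arm), fit_reml(d, n_dead_day10 / n_nymphs))
      bundle$vc[[arm]] <- fit
      if ("degenerate" %in% fit$flags || !fit$converged) {
        bundle$heritability[[arm]] <- list(h2 = NA_real_, status = "not estimable",
                                           reason = "degenerate or unconverged fit")
        results$survival[[arm]] <- list(
          mortality = mean(d$n_dead_day10) / mean(d$n_nymphs),
          variance_components = as.list(setNames(fit$components$variance, fit$components$term)),
          heritability = "not estimable",
          reason = "degenerate or unconverged fit"
        )
        next
      }
      h2 <- stage(paste0("heritability_", arm), h2_pipeline(fit))
      h2$status <- "ok"
      bundle$heritability[[arm]] <- h2
      results$survival[[arm]] <- list(
        mortality = mean(d$n_dead_day10) / mean(d$n_nymphs),
        variance_components = as.list(setNames(fit$components$variance, fit$components$term)),
        variance_shares_pct = as.list(setNames(fit$components$share_pct, fit$components$term)),
        heritability = h2$h2,
        V_A = h2$V_A, V_D = h2$V_D, V_Ec = h2$V_Ec, V_e = h2$V_e, V_P = h2$V_P,
        flags = h2$flags
      )
    }
  }

  if (!is.null(life)) {
    stage("write_life_history", write_tables(list(life_history = life), out_dir))
    bundle$life_history <- life
    bundle$costs <- stage("summarize_costs", summarize_costs(life))
    # treatment test on the additive scale (df = 1); the interaction is
    # reported by fit_fecundity itself when wanted
    fec_full <- stage("fecundity_fit",
                      fit_fecundity(life,
                                    formula = eggs_laid ~ treatment + factor(disk_day),
                                    mode = "robust"))
    fec_red <- stage("fecundity_reduced",
                     fit_fecundity(life, formula = eggs_laid ~ factor(disk_day),
                                   mode = "robust"))
    bundle$fecundity <- fec_full
    bundle$fecundity_lr <- lr_test(fec_full, fec_red)
    ht <- hatch_totals(life)
    hat_full <- stage("hatch_fit", fit_hatch(ht, hatched, unhatched, ~treatment))
    hat_red <- stage("hatch_reduced", fit_hatch(ht, hatched, unhatched, ~1))
    bundle$hatch <- hat_full
    bundle$hatch_lr <- lr_test(hat_full, hat_red)
    results$life_history <- list(
      mean_total_eggs = as.list(setNames(bundle$costs$fecundity$mean_total_eggs,
                                         bundle$costs$fecundity$treatment)),
      hatch_proportion = as.list(setNames(bundle$costs$hatch$proportion,
                                          bundle$costs$hatch$treatment)),
      fecundity_treatment_lr = as.list(bundle$fecundity_lr),
      hatch_treatment_lr = as.list(bundle$hatch_lr)
    )
  }

  bundle$results <- results
  rep <- report(bundle)
  writeLines(rep$markdown, file.path(out_dir, "report.md"))
  jsonlite::write_json(rep$json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("hostresist")),
    mode = mode,
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) {
      x <- unclass(config)
      x$life_history <- unclass(x$life_history)
      x$ec_share <- as.list(x$ec_share)
      x$life_history$hatch_day_probs <- as.list(x$life_history$hatch_day_probs)
      x
    } else {
      NULL
    },
    digests = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  names(manifest$digests) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  bundle$manifest <- manifest
  bundle$out_dir <- out_dir
  bundle$degenerate <- any(vapply(bundle$heritability, function(h) {
    !is.null(h$status) && h$status != "ok"
  }, logical(1)))
  class(bundle) <- "run_bundle"
  invisible(bundle)
}

#' Render the results report
#'
#' Builds a markdown report (variance-share table in descending order,
#' heritability with flags, life-history cost tables) and the matching JSON
#' record from a pipeline bundle. The JSON is checked against the schema
#' shipped in `inst/extdata/results-schema.json`.
#'
#' @param bundle A `run_bundle` (or a compatible list).
#' @return List with elements `markdown` (character vector of lines) and
#'   `json` (the validated results list).
#' @export
report <- function(bundle) {
  res <- bundle$results %||% abort("bundle carries no results")
  md <- c("# Parasitism-resistance analysis report", "")

  if (!is.null(res$treatment_effect)) {
    te <- res$treatment_effect
    md <- c(md, "## Treatment effect on mortality", "",
            sprintf("Exposure log-odds effect: %.3f (Wald chi-square = %.2f, df = %d, p = %.3g).",
                    te$log_odds, te$statistic, te$df, te$p_value),
            paste0("_", te$note, "_"), "")
  }

  for (arm in names(res$survival %||% list())) {
    s <- res$survival[[arm]]
    md <- c(md, sprintf("## Variance components: %s arm", arm), "",
            sprintf("Pooled mortality: %.1f%%.", 100 * s$mortality), "")
    if (!is.null(s$variance_shares_pct)) {
      sh <- unlist(s$variance_shares_pct)
      sh <- sort(sh, decreasing = TRUE)
      md <- c(md, "| component | % of variance |", "|---|---|",
              sprintf("| %s | %.1f |", names(sh), sh), "")
    }
    if (identical(s$heritability, "not estimable")) {
      md <- c(md, sprintf("Heritability: **not estimable** (%s).", s$reason), "")
    } else {
      fl <- if (length(s$flags) > 0) paste0(" (flags: ", paste(s$flags, collapse = ", "), ")") else ""
      md <- c(md, sprintf("Narrow-sense heritability (haplodiploid-adjusted): **h2 = %.2f**%s.",
                          s$heritability, fl), "")
    }
  }

  if (!is.null(res$life_history)) {
    lh <- res$life_history
    md <- c(md, "## Life-history costs", "",
            "| arm | mean total eggs | hatch proportion |", "|---|---|---|")
    for (arm in names(lh$mean_total_eggs)) {
      md <- c(md, sprintf("| %s | %.2f | %.3f |", arm,
                          lh$mean_total_eggs[[arm]], lh$hatch_proportion[[arm]]))
    }
    md <- c(md, "",
            sprintf("Fecundity treatment LR: chi-square = %.2f (df = %d), p = %.3g.",
                    lh$fecundity_treatment_lr$statistic, lh$fecundity_treatment_lr$df,
                    lh$fecundity_treatment_lr$p.value),
            sprintf("Hatch-success treatment LR: chi-square = %.2f (df = %d), p = %.3g.",
                    lh$hatch_treatment_lr$statistic, lh$hatch_treatment_lr$df,
                    lh$hatch_treatment_lr$p.value), "")
  } else {
    message("life-history section empty: omitted from report")
  }

  validate_results_json(res)
  list(markdown = md, json = res)
}

#' Validate a results record against the shipped schema
#'
#' Structural validation (required fields and types) against
#' `inst/extdata/results-schema.json`.
#'
#' @param res Results list as produced inside [run_pipeline()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_results_json <- function(res) {
  schema_path <- system.file("extdata", "results-schema.json", package = "hostresist")
  if (schema_path == "") {
    schema_path <- file.path("inst", "extdata", "results-schema.json")
  }
  schema <- jsonlite::read_json(schema_path)
  check_node <- function(node, spec, path) {
    for (fld in names(spec$required %||% list())) {
      sub <- spec$required[[fld]]
      if (is.null(node[[fld]])) abort(paste0("results JSON: missing `", path, fld, "`"))
      val <- node[[fld]]
      type <- if (is.character(sub)) sub else sub$type
      ok <- switch(type,
        number = is.numeric(val) || identical(val, "not estimable"),
        string = is.character(val),
        object = is.list(val),
        any = TRUE,
        TRUE
      )
      if (!ok) abort(paste0("results JSON: `", path, fld, "` has wrong type (need ", type, ")"))
      if (is.list(sub) && !is.null(sub$required)) {
        check_node(val, sub, paste0(path, fld, "."))
      }
    }
    invisible(TRUE)
  }
  for (top in names(schema$sections)) {
    if (!is.null(res[[top]])) check_node(res[[top]], schema$sections[[top]], paste0(top, "."))
  }
  invisible(TRUE)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>", x$mode, "mode; outputs in", x$out_dir, "\n")
  for (arm in names(x$heritability %||% list())) {
    h <- x$heritability[[arm]]
    if (!is.null(h$status) && h$status == "ok") {
      cat(sprintf("  %s arm: h2 = %.3f\n", arm, h$h2))
    } else {
      cat(sprintf("  %s arm: heritability %s\n", arm, h$status %||% "?"))
    }
  }
  if (!is.null(x$costs)) {
    f <- x$costs$fecundity
    cat(sprintf("  eggs: %s\n",
                paste(sprintf("%s %.1f", f$treatment, f$mean_total_eggs), collapse = ", ")))
  }
  invisible(x)
}
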