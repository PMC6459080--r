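#' Pipeline configuration
#'
#' Bundles the simulation block with the analysis options for
#' [run_pipeline()].  For simulation runs the seed is mandatory (it lives
#' in the `sim` block).
#'
#' @param sim A [sim_config()] object.
#' @param traits Trait columns analysed downstream.
#' @param n_pc Structure PCs for the GWAS (default 3).
#' @param fdr GWAS q-value threshold (default 0.05).
#' @param model Prediction model (default `"rrblup"`).
#' @param preset MCMC preset for Bayesian models (default `"reduced"`).
#' @param gwas,prediction Stage switches.
#' @param gwas_traits,prediction_traits Subsets of `traits` run through the
#'   heavier stages (defaults: `dl_mean` and `LOI`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim,
                            traits = c("LOI", "LOS", "LI", "dl_mean",
                                       "dl_mix"),
                            n_pc = 3, fdr = 0.05, model = "rrblup",
                            preset = "reduced", gwas = TRUE,
                            prediction = TRUE,
                            gwas_traits = c("dl_mean", "LOI"),
                            prediction_traits = c("dl_mean", "LOI")) {
  validate_sim_config(sim)
  structure(list(sim = sim, traits = traits, n_pc = n_pc, fdr = fdr,
                 model = model, preset = preset, gwas = gwas,
                 prediction = prediction, gwas_traits = gwas_traits,
                 prediction_traits = prediction_traits),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML must contain a `sim` block (arguments of [sim_config()]) and
#' may override any analysis option of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$sim)) stop("config must contain a 'sim' block")
  if (is.null(raw$sim$seed)) stop("simulation runs require a seed")
  sim <- do.call(sim_config, raw$sim)
  opts <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), opts))
}

#' Run the full simulate-score-validate-GWAS-predict pipeline
#'
#' Executes every stage on a synthetic field and returns (and optionally
#' writes) the report bundle: the per-plot score table, per-trial
#' heritabilities, the digital-vs-visual correlation matrix, GWAS results,
#' and the cross-validated prediction accuracy table.  Any stage failure
#' aborts with a stage-tagged error; partial outputs written so far are
#' retained next to a `FAILED` marker file.
#'
#' @param config A `pipeline_config` (or a bare [sim_config()], wrapped
#'   with defaults).
#' @param out_dir Optional output directory for the CSV/JSON artifacts.
#' @return List of class `pipeline_bundle`: `scores`, `heritability`,
#'   `correlations`, `blues`, `gwas`, `prediction`, `tags_called`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (inherits(config, "sim_config")) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    msg <- function(...) message(sprintf("[%s] %s %s",
                                         format(Sys.time(),
                                                "%Y-%m-%dT%H:%M:%S"),
                                         name, paste0(...)))
    msg("start")
    res <- tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste("failed at stage:", name, "-",
                         conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    msg("done")
    res
  }

  field <- stage("simulate", simulate_field(config$sim))
  digital <- stage("lodging",
                   score_plots(field$pre, field$post, field$layout))
  scores <- merge(digital, field$visual, by = "plot_id", sort = FALSE)
  scores <- merge(scores,
                  field$lodging[, c("plot_id", "true_dl",
                                    "lodged_fraction")],
                  by = "plot_id", sort = FALSE)
  scores <- scores[match(field$layout$plot_id, scores$plot_id), ]

  herit <- stage("stats", trial_heritability(scores, config$traits))
  corr <- stage("stats", pearson_matrix(scores[, config$traits]))

  blues <- stage("stats", {
    out <- lapply(config$traits, function(tr) compute_blues(scores, tr))
    names(out) <- config$traits
    out
  })

  qc <- stage("genotype-qc", impute_and_clean(filter_markers(field$genotypes)))
  K <- stage("kinship", genomic_relationship(qc))

  gwas_res <- NULL
  if (config$gwas) {
    gwas_res <- stage("gwas", {
      lapply(stats::setNames(config$gwas_traits, config$gwas_traits),
             function(tr) gwas_scan(blues[[tr]], qc, K = K,
                                    n_pc = config$n_pc))
    })
  }

  tags_called <- stage("2ns", call_2ns(field$tags))

  pred <- NULL
  if (config$prediction) {
    pred <- stage("predict", {
      scheme <- make_trial_folds(field$layout)
      rows <- lapply(config$prediction_traits, function(tr) {
        vc <- reml_variance_components(
          scores[[tr]], scores$entry_id,
          interaction(scores$trial, scores$rep, scores$subblock,
                      drop = TRUE))
        H2 <- entry_mean_heritability(vc, config$sim$n_reps)$H2
        res <- cross_validate(config$model, qc, blues[[tr]], scheme,
                              H2 = H2, seed = config$sim$seed,
                              preset = config$preset)
        res$trait <- tr
        res
      })
      do.call(rbind, rows)
    })
  }

  manifest <- list(
    seed = config$sim$seed,
    config_hash = sum(utils::head(utf8ToInt(
      paste(yaml::as.yaml(unclass(config$sim)), collapse = "")), 10000)),
    package_version = as.character(utils::packageVersion("lodgepipe")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_plots = nrow(scores)
  )

  bundle <- structure(list(scores = scores, heritability = herit,
                           correlations = corr, blues = blues,
                           gwas = gwas_res, prediction = pred,
                           tags_called = tags_called,
                           manifest = manifest),
                      class = "pipeline_bundle")
  if (!is.null(out_dir)) {
    stage("write", {
      utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                       row.names = FALSE)
      utils::write.csv(herit, file.path(out_dir, "heritability.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(corr$r),
                       file.path(out_dir, "correlation_matrix.csv"))
      if (!is.null(gwas_res)) {
        for (tr in names(gwas_res)) {
          utils::write.csv(gwas_res[[tr]],
                           file.path(out_dir, sprintf("gwas_%s.csv", tr)),
                           row.names = FALSE)
        }
      }
      if (!is.null(pred)) {
        utils::write.csv(pred, file.path(out_dir, "prediction.csv"),
                         row.names = FALSE)
      }
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      writeLines(make_report(bundle), file.path(out_dir, "report.md"))
    })
  }
  bundle
}

#' Render a human-readable report from a pipeline bundle
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param fdr q-value threshold used in the discovery section
#'   (default 0.05).
#' @return Character vector of markdown lines.
#' @export
make_report <- function(bundle, fdr = 0.05) {
  required <- c("scores", "heritability", "correlations", "manifest")
  missing <- setdiff(required, names(bundle)[!vapply(bundle, is.null,
                                                     logical(1))])
  if (length(missing) > 0) {
    stop("report bundle is missing member(s): ",
         paste(missing, collapse = ", "))
  }
  measures <- c("LOI", "LOS", "LI", "dl_mean", "dl_mix")
  lines <- c(
    "# Digital lodging pipeline report",
    "",
    sprintf("Seed %s, %d plots, package %s, created %s.",
            bundle$manifest$seed, bundle$manifest$n_plots,
            bundle$manifest$package_version, bundle$manifest$created),
    "",
    "## Lodging measures",
    "",
    paste("Scored per plot:", paste(measures, collapse = ", "),
          "(visual incidence, severity, index; digital mean and mixture)."),
    "",
    "## Trait distributions",
    ""
  )
  for (m in intersect(measures, names(bundle$scores))) {
    v <- bundle$scores[[m]]
    lines <- c(lines, sprintf(
      "- %s: mean %.3f, sd %.3f, range [%.3f, %.3f]",
      m, mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
      min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  lines <- c(lines, "", "## Per-trial entry-mean heritability", "")
  h <- bundle$heritability
  for (tr in unique(h$trait)) {
    hh <- h$H2[h$trait == tr]
    lines <- c(lines, sprintf("- %s: mean H2 = %.2f (range %.2f-%.2f over %d trials)",
                              tr, mean(hh), min(hh), max(hh), length(hh)))
  }
  lines <- c(lines, "", "## Digital vs visual correlations", "")
  r <- bundle$correlations$r
  if (all(c("dl_mean", "LOI") %in% rownames(r))) {
    lines <- c(lines,
               sprintf("- r(DLmean, LOI) = %.2f", r["dl_mean", "LOI"]),
               sprintf("- r(DLmix, LOI) = %.2f", r["dl_mix", "LOI"]),
               sprintf("- r(DLmean, DLmix) = %.2f", r["dl_mean", "dl_mix"]))
  }
  lines <- c(lines, "", "## GWAS", "")
  if (is.null(bundle$gwas) || length(bundle$gwas) == 0) {
    lines <- c(lines, "GWAS stage not run.")
  } else {
    for (tr in names(bundle$gwas)) {
      g <- bundle$gwas[[tr]]
      nd <- sum(g$q <= fdr, na.rm = TRUE)
      lines <- c(lines, if (nd == 0) {
        sprintf("- %s: no discoveries at q <= %.2f.", tr, fdr)
      } else {
        top <- g[which.min(g$p), ]
        sprintf("- %s: %d discoveries at q <= %.2f; top marker %s (chr %s, p = %.2e).",
                tr, nd, fdr, top$marker_id, top$chrom, top$p)
      })
    }
  }
  lines <- c(lines, "", "## Genomic prediction", "")
  if (is.null(bundle$prediction)) {
    lines <- c(lines, "Prediction stage not run.")
  } else {
    p <- bundle$prediction
    for (i in seq_len(nrow(p))) {
      lines <- c(lines, sprintf(
        "- %s (%s, %s): r_pv = %.2f, H2 = %.2f, r_pa = %.2f",
        p$trait[i], p$model[i], p$scheme[i], p$r_pv[i], p$H2[i],
        p$r_pa[i]))
    }
  }
  lines
}
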