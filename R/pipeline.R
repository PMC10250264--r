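#' Read a pipeline run configuration
#'
#' Configurations are YAML or JSON; see [run_pipeline()] for the recognized
#' fields.
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("config must be YAML or JSON: %s", path)
  }
}

#' Run the full reliability pipeline
#'
#' Orchestrates simulate/load, scoring with exclusions, descriptives,
#' test-retest coefficients per group, split-half estimates (both splitting
#' methods), reliability-by-length curves with Spearman-Brown fits,
#' correlation-comparison tests between named group pairs, and the power
#' table. Every stochastic stage derives its seed from the master seed, and
#' the report records all of them, so the same configuration reproduces the
#' same numbers.
#'
#' Recognized configuration fields:
#' \describe{
#'   \item{`input`}{Path to a trial-level CSV (see [read_trials()]); or}
#'   \item{`simulate`}{A list of group simulations, each a list of
#'     [flanker_params()] arguments plus a `group` label.}
#'   \item{`seed`}{Master seed (mandatory when any stage is stochastic and
#'     no per-stage seed is given).}
#'   \item{`stages`}{Subset of `c("descriptives", "test_retest",
#'     "splithalf", "lengthcurve", "compare", "power")`; scoring always
#'     runs. Default: all but `lengthcurve`.}
#'   \item{`splithalf`}{List: `n_replications` (default 10000), `methods`,
#'     `session`, `aggregate`, `adjust`.}
#'   \item{`lengthcurve`}{List: `lengths`, `n_replications` (default 10000),
#'     `methods`.}
#'   \item{`compare`}{List of tests, each
#'     `list(groups = c(g1, g2), alternative, label)`, comparing test-retest
#'     ICCs via [compare_correlations()].}
#'   \item{`power`}{List or list-of-lists of [required_n_per_group()]
#'     arguments.}
#' }
#'
#' @param config Named list or a path accepted by [read_run_config()].
#' @param out_dir Optional directory; when given, writes `scores.csv`,
#'   `exclusions.csv` and `report.json` there.
#' @return The report (a named list), invisibly when `out_dir` is given.
#' @examples
#' cfg <- list(
#'   simulate = list(list(group = "sim", n_participants = 12, seed = 3)),
#'   seed = 1, stages = c("descriptives", "test_retest", "power"),
#'   power = list(q_effect = 0.3, alpha = 0.05, power = 0.8)
#' )
#' rep <- run_pipeline(cfg)
#' rep$test_retest
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) stopf("config must be a list or a file path")
  stages <- config$stages %||%
    c("descriptives", "test_retest", "splithalf", "compare", "power")
  known <- c("descriptives", "test_retest", "splithalf", "lengthcurve",
             "compare", "power")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stopf("unknown stage(s): %s (known: %s)",
          paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }
  seed <- config$seed %||% 1L
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("flankrel")),
      master_seed = seed,
      stages = stages,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    )
  )

  # --- data -----------------------------------------------------------------
  trials <- if (!is.null(config$input)) {
    read_trials(config$input)
  } else if (!is.null(config$simulate)) {
    sims <- config$simulate
    if (!is.null(sims$group) || !is.null(sims$n_participants)) sims <- list(sims)
    do.call(rbind, lapply(seq_along(sims), function(i) {
      s <- sims[[i]]
      grp <- s$group %||% sprintf("group%d", i)
      s$group <- NULL
      if (is.null(s$seed)) s$seed <- derive_seed(seed, paste0("sim_", grp))
      sim <- simulate_flanker(do.call(flanker_params, s), group = grp)
      # participant ids must be unique across groups
      sim$participant <- paste(grp, sim$participant, sep = ":")
      sim
    }))
  } else {
    stopf("config needs either `input` (CSV path) or `simulate` (group specs)")
  }

  # --- scoring and exclusions ----------------------------------------------
  flagged <- flag_rt_exclusions(trials)
  scores <- score_participants(flagged)
  excl <- exclude_participants(scores)
  scores_kept <- scores[scores$participant %in% excl$retained, ]
  flagged_kept <- flagged[flagged$participant %in% excl$retained, ]
  groups <- sort(unique(scores_kept$group))
  report$exclusions <- list(
    n_total = nrow(excl$report),
    n_retained = length(excl$retained),
    n_excluded_accuracy = sum(excl$report$status == "excluded_accuracy"),
    n_incomplete = sum(excl$report$status == "incomplete")
  )
  message(sprintf("scored %d participants; retained %d (%d accuracy, %d incomplete excluded)",
                  nrow(excl$report), length(excl$retained),
                  report$exclusions$n_excluded_accuracy,
                  report$exclusions$n_incomplete))

  if ("descriptives" %in% stages) {
    report$descriptives <- group_descriptives(scores_kept)
  }

  if ("test_retest" %in% stages) {
    report$test_retest <- lapply(setNames(groups, groups), function(g) {
      w <- effects_wide(scores_kept[scores_kept$group == g, ])
      icc <- icc_absolute_agreement(w$s1, w$s2)
      r <- pearson_reliability(w$s1, w$s2)
      list(n = nrow(w), icc_abs_agreement = icc$value, pearson = r$value)
    })
  }

  if ("splithalf" %in% stages) {
    sh <- config$splithalf %||% list()
    methods <- sh$methods %||% c("permutated", "monte_carlo")
    report$splithalf <- lapply(setNames(groups, groups), function(g) {
      lapply(setNames(methods, methods), function(m) {
        spec <- split_spec(
          method = m,
          n_replications = sh$n_replications %||% 10000,
          adjust = sh$adjust %||% "spearman_brown",
          aggregate = sh$aggregate %||% "mean",
          session = sh$session %||% 1,
          seed = derive_seed(seed, paste("sh", g, m))
        )
        est <- splithalf_reliability(
          flagged_kept[flagged_kept$group == g, ], spec)
        list(estimate = est$value, n = est$n_participants,
             n_replications = spec$n_replications, seed = spec$seed,
             n_dropped = est$meta$n_dropped_replications)
      })
    })
  }

  if ("lengthcurve" %in% stages) {
    lc <- config$lengthcurve %||% list()
    methods <- lc$methods %||% c("test_retest", "permutated", "monte_carlo")
    report$lengthcurve <- lapply(setNames(groups, groups), function(g) {
      lapply(setNames(methods, methods), function(m) {
        spec <- split_spec(seed = derive_seed(seed, paste("lc", g, m)))
        curve <- reliability_curve(
          flagged_kept[flagged_kept$group == g, ], method = m,
          lengths = lc$lengths %||% seq(40L, 320L, by = 40L),
          n_replications = lc$n_replications %||% 10000,
          spec = spec
        )
        curve <- fit_spearman_brown_curve(curve)
        list(lengths = curve$lengths, estimates = curve$estimates,
             best_fit_rho = curve$best_fit_rho, sse = curve$sse,
             seed = spec$seed)
      })
    })
  }

  if ("compare" %in% stages && !is.null(config$compare)) {
    if (is.null(report$test_retest)) {
      stopf("`compare` needs the test_retest stage")
    }
    cmp <- config$compare
    if (!is.null(cmp$groups)) cmp <- list(cmp)
    report$comparisons <- lapply(cmp, function(cc) {
      gs <- cc$groups
      if (length(gs) != 2L || !all(gs %in% groups)) {
        stopf("compare entry must name two known groups (known: %s)",
              paste(groups, collapse = ", "))
      }
      tr <- report$test_retest
      res <- compare_correlations(
        tr[[gs[1]]]$icc_abs_agreement, tr[[gs[1]]]$n,
        tr[[gs[2]]]$icc_abs_agreement, tr[[gs[2]]]$n,
        alternative = cc$alternative %||% "greater"
      )
      c(list(label = cc$label %||% paste(gs, collapse = " vs "),
             groups = gs), res)
    })
  }

  if ("power" %in% stages) {
    pw <- config$power %||% list(q_effect = 0.3, alpha = 0.05, power = 0.8)
    if (!is.null(pw$q_effect)) pw <- list(pw)
    report$power <- lapply(pw, function(row) {
      list(q_effect = row$q_effect, alpha = row$alpha %||% 0.05,
           power = row$power %||% 0.8,
           n_per_group = required_n_per_group(row$q_effect,
                                              row$alpha %||% 0.05,
                                              row$power %||% 0.8))
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(scores_kept, file.path(out_dir, "scores.csv"))
    data.table::fwrite(excl$report, file.path(out_dir, "exclusions.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
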