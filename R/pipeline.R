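# End-to-end pipeline: simulate (or ingest) -> validate -> trim -> learning
# metrics -> posttest scoring -> group inference -> markdown report.

group_factors <- function(group) {
  tibble::tibble(
    group = group,
    knowledge = ifelse(grepl("^PK", group), "PK", "NPK"),
    sequence = ifelse(grepl("Fixed", group), "Fixed", "Prob")
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage of the standard analysis on a simulated cohort (the
#' default) or on an ingested trial CSV: structural validation, SD-rule
#' trimming, the learning decomposition (with probability-stratified
#' variants for probabilistic groups), posttest scoring with chance
#' correction, and group-level inference (factorial ANOVAs on the learning
#' measures, the Scheirer-Ray-Hare test on recognition, tests against
#' chance on recall and recognition). A failed stage marks the bundle
#' incomplete and skips the stages that depend on it.
#'
#' @param config An [srt_config()].
#' @param out_dir Optional directory: when given, all tables, the markdown
#'   report and a run record (config hash, seed, package version) are
#'   written there.
#' @return A list of class `srt_pipeline_result` with elements `trials`,
#'   `trim_report`, `summary` (per-participant learning summary),
#'   `summary_stratified`, `posttest_scores`, `stats` (named list of test
#'   objects/tibbles), `report` (markdown lines), `complete`, `failed_stage`.
#' @export
run_srt_pipeline <- function(config = srt_config(), out_dir = NULL) {
  stopifnot(inherits(config, "srt_pipeline_config"))
  res <- list(complete = TRUE, failed_stage = NA_character_)
  stage <- function(name, expr) {
    if (!res$complete) return(NULL)
    out <- tryCatch(expr, error = function(e) {
      warn(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
      res$complete <<- FALSE
      res$failed_stage <<- name
      NULL
    })
    out
  }

  groups <- config$groups
  designs <- NULL
  cohort <- NULL
  trials <- stage("input", {
    if (!is.null(config$simulation)) {
      groups <- groups %||% cohort_presets(config$simulation)
      cohort <- simulate_cohort(groups, seed = config$seed)
      designs <- lapply(groups, `[[`, "design")
      cohort$trials
    } else if (!is.null(config$input_trials)) {
      read_trial_csv(config$input_trials)
    } else {
      abort("Either `simulation` or `input_trials` must be supplied.")
    }
  })

  stage("validate", {
    issues <- validate_trial_table(trials)
    if (nrow(issues) > 0) {
      abort(paste(
        "Trial table failed validation:",
        paste(issues$issue, collapse = ", ")
      ))
    }
    invisible(NULL)
  })

  trimmed <- stage("trim", trim_rts(trials, k = config$trim_k))
  res$trials <- trimmed
  res$trim_report <- if (!is.null(trimmed)) trim_report(trimmed)

  res$summary <- stage("metrics", {
    learning_summary(trimmed,
      window = config$window,
      online_blocks = config$online_blocks,
      offline_from_blocks = config$offline_from_blocks
    )
  })

  res$summary_stratified <- stage("metrics_stratified", {
    prob_groups <- if (!is.null(designs)) {
      names(designs)[vapply(
        designs, function(d) d$sequence_type == "probabilistic", logical(1)
      )]
    } else if ("transition_prob" %in% names(trimmed)) {
      unique(trimmed$group[!is.na(trimmed$transition_prob)])
    } else {
      character(0)
    }
    if (length(prob_groups) == 0) {
      NULL
    } else {
      trimmed |>
        dplyr::filter(.data$group %in% prob_groups) |>
        stratify_by_probability(probs = c(0.3, 0.6)) |>
        learning_summary(
          window = config$window,
          online_blocks = config$online_blocks,
          offline_from_blocks = config$offline_from_blocks
        )
    }
  })

  res$posttest_scores <- stage("posttest", {
    pt <- if (!is.null(cohort)) {
      cohort$posttest
    } else if (!is.null(config$input_posttest)) {
      readr::read_csv(config$input_posttest, show_col_types = FALSE)
    } else {
      NULL
    }
    if (is.null(pt) || is.null(designs)) {
      NULL
    } else {
      purrr::map_dfr(names(designs), function(g) {
        score_posttest(pt[pt$group == g, ], designs[[g]])
      })
    }
  })

  res$stats <- stage("stats", if (is.null(res$summary)) NULL else {
    smr <- dplyr::left_join(res$summary, group_factors(res$summary$group),
      by = "group"
    )
    out <- list()
    for (m in c("online", "offline", "corrected_offline")) {
      out[[paste0("anova_", m)]] <-
        two_way_anova(smr, m, c("knowledge", "sequence"))
    }
    if (!is.null(res$posttest_scores)) {
      ps <- dplyr::left_join(
        res$posttest_scores, group_factors(res$posttest_scores$group),
        by = "group"
      )
      out$anova_recall <-
        two_way_anova(ps, "recall_percent_corrected", c("knowledge", "sequence"))
      out$srh_recognition <-
        scheirer_ray_hare(ps, "recognition_score", c("knowledge", "sequence"))
      chance_by_group <- vapply(
        setNames(nm = unique(ps$group)),
        function(g) {
          if (!is.null(designs) && g %in% names(designs)) {
            recall_chance_level(designs[[g]])
          } else {
            NA_real_
          }
        }, numeric(1)
      )
      out$recall_vs_chance <- test_against_chance(
        ps, "recall_percent", "group", chance_by_group,
        method = "t", alpha = config$alpha
      )
      out$recognition_vs_chance <- test_against_chance(
        ps, "recognition_score", "group",
        recognition_chance_level(),
        method = "wilcoxon", alpha = config$alpha
      )
    }
    out
  })

  res$report <- stage("report", pipeline_report(res))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$trials)) {
      write_trial_csv(res$trials, file.path(out_dir, "trials.csv"))
    }
    write_if <- function(x, name) {
      if (!is.null(x)) readr::write_csv(x, file.path(out_dir, name))
    }
    write_if(res$trim_report, "trim_report.csv")
    write_if(res$summary, "learning_summary.csv")
    write_if(res$summary_stratified, "learning_summary_stratified.csv")
    write_if(res$posttest_scores, "posttest_scores.csv")
    if (!is.null(res$stats)) {
      stats_tbl <- purrr::imap_dfr(res$stats, function(x, nm) {
        tb <- if (inherits(x, "srt_anova") || inherits(x, "srt_rank_test")) {
          tidy(x)
        } else {
          x
        }
        dplyr::mutate(tb, analysis = nm, .before = 1)
      })
      readr::write_csv(stats_tbl, file.path(out_dir, "statistics.csv"))
    }
    if (!is.null(res$report)) {
      writeLines(res$report, file.path(out_dir, "report.md"))
    }
    record <- list(
      config_hash = rlang::hash(config),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("srtlearn")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      complete = res$complete
    )
    jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  class(res) <- "srt_pipeline_result"
  res
}

md_table <- function(df, digits = 1) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

pipeline_report <- function(res) {
  lines <- c("# SRT pipeline report", "")
  if (!is.null(res$trials)) {
    bm <- block_means(res$trials)
    gm <- bm |>
      dplyr::group_by(.data$group, .data$block) |>
      dplyr::summarise(mean_rt = mean(.data$mean_rt, na.rm = TRUE), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "block", values_from = "mean_rt", names_prefix = "B")
    lines <- c(lines, "## Group-by-block mean RT (ms)", "", md_table(gm), "")
  }
  if (!is.null(res$summary)) {
    ls <- res$summary |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(dplyr::across(
        c("learning_b1_b4", "interference_b5_b4", "online", "offline",
          "corrected_offline"),
        ~ mean(.x, na.rm = TRUE)
      ), .groups = "drop")
    lines <- c(lines, "## Learning decomposition (group means, ms)", "",
      md_table(ls), "")
  }
  if (!is.null(res$posttest_scores)) {
    ps <- res$posttest_scores |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        recognition = mean(.data$recognition_score),
        recall = mean(.data$recall_percent),
        recall_corrected = mean(.data$recall_percent_corrected),
        .groups = "drop"
      )
    lines <- c(lines, "## Posttest (group means)", "", md_table(ps, 3), "")
  }
  if (!is.null(res$stats)) {
    for (nm in names(res$stats)) {
      x <- res$stats[[nm]]
      tb <- if (inherits(x, "srt_anova") || inherits(x, "srt_rank_test")) {
        tidy(x)
      } else {
        x
      }
      lines <- c(lines, paste("##", nm), "", md_table(tb, 4), "")
    }
  }
  if (!res$complete) {
    lines <- c(lines, sprintf("**Incomplete run: stage '%s' failed.**", res$failed_stage))
  }
  lines
}

#' @export
print.srt_pipeline_result <- function(x, ...) {
  cat("<srt_pipeline_result>",
    if (x$complete) "complete" else paste0("INCOMPLETE (", x$failed_stage, ")"),
    "\n")
  if (!is.null(x$summary)) {
    cat("  participants:", nrow(x$summary), "\n")
  }
  invisible(x)
}
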