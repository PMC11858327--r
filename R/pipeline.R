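#' Configuration for an end-to-end pipeline run
#'
#' @param input a cohort CSV path, a cohort data frame, or a
#'   [cohort_spec()] (which is simulated first).
#' @param population which analysis populations to report: `"all_case"`,
#'   `"complete_case"`, or `"both"`. The four-group tables always use the
#'   all-case population; the setting controls the ROC summary table.
#' @param crp_cutoff `"youden"` (select the cut-off by the Youden index on
#'   the all-case, all-diagnoses, days 0-2 window) or a fixed cut-off in
#'   mg/dL (> 0).
#' @param alpha significance level applied to the adjusted pairwise
#'   p-values, in (0, 1).
#' @param seed integer seed; overrides the seed of a `cohort_spec` input
#'   when not NULL. All pipeline randomness flows from it.
#' @param output_dir directory for the report CSVs; created if absent.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, population = "both", crp_cutoff = "youden",
                       alpha = 0.05, seed = NULL, output_dir = NULL) {
  if (!population %in% c("all_case", "complete_case", "both"))
    stop("population must be one of all_case, complete_case, both",
         call. = FALSE)
  if (is.numeric(crp_cutoff)) {
    if (length(crp_cutoff) != 1 || is.na(crp_cutoff) || crp_cutoff <= 0)
      stop("a fixed crp_cutoff must be a single value > 0", call. = FALSE)
  } else if (!identical(crp_cutoff, "youden")) {
    stop("crp_cutoff must be \"youden\" or a positive number", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(input = input, population = population,
                 crp_cutoff = crp_cutoff, alpha = alpha, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: (optional) cohort simulation, eligibility
#' filtering with an attrition table, diagnosis categorisation, severity
#' scoring, CRP interpolation and windowed features, outcome derivation,
#' the population x window x subgroup ROC summary, CRP cut-off selection,
#' four-group classification, characteristics and outcome tables, and the
#' Kruskal-Wallis / Conover-Iman p-value table. Identical config + input
#' always produce identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with `cohort` (the included, fully annotated
#'   cohort), `attrition`, `table1` (ROC summary), `cutoff`,
#'   `table2` (characteristics), `table3` (outcomes), `pvalues`,
#'   `comparisons` (raw [compare_four_groups()] output), and `metadata`.
#'   If `config$output_dir` is set, the tables are also written as CSVs
#'   (attrition.csv, cohort_included.csv, table1_auc.csv,
#'   table2_characteristics.csv, table3_outcomes.csv, pvalues.csv,
#'   run_metadata.csv).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  input <- config$input
  if (inherits(input, "cohort_spec")) {
    if (!is.null(config$seed)) input$seed <- config$seed
    raw <- simulate_cohort(input)
  } else if (is.character(input)) {
    raw <- read_cohort_csv(input)
  } else if (is.data.frame(input)) {
    missing_cols <- setdiff(cohort_columns(), names(input))
    if (length(missing_cols))
      stop("cohort schema mismatch; missing: [",
           paste(missing_cols, collapse = ", "), "]", call. = FALSE)
    raw <- input
  } else {
    stop("input must be a path, data frame or cohort_spec", call. = FALSE)
  }

  built <- build_cohort(raw)
  cohort <- built$included
  if (nrow(cohort) == 0L)
    stop("no admissions remain after eligibility filtering", call. = FALSE)
  cohort <- add_severity(cohort)
  cohort <- add_crp_features(cohort)
  cohort <- add_outcome_flags(cohort)

  table1 <- windowed_subgroup_analysis(cohort)
  if (config$population != "both")
    table1 <- table1[table1$population == config$population, , drop = FALSE]

  cutoff <- if (is.numeric(config$crp_cutoff)) {
    config$crp_cutoff
  } else {
    yo <- youden_optimal(build_roc(cohort$crp_max_d02, cohort$composite))
    yo$optimal_cutoff
  }
  cohort <- add_four_group(cohort, cutoff)

  comparisons <- compare_four_groups(cohort)
  table2 <- characteristics_table(cohort)
  table3 <- outcomes_table(comparisons)
  pvals <- pvalue_table(comparisons)

  metadata <- data.frame(
    key = c("population", "crp_cutoff_setting", "crp_cutoff_used", "alpha",
            "seed", "n_input", "n_included", "n_complete_case", "version"),
    value = c(config$population, as.character(config$crp_cutoff),
              format(cutoff), format(config$alpha),
              ifelse(is.null(config$seed), "", format(config$seed)),
              nrow(raw), nrow(cohort), sum(cohort$complete_case),
              as.character(utils::packageVersion("glimcrp"))),
    stringsAsFactors = FALSE)

  result <- list(cohort = cohort, attrition = built$attrition,
                 table1 = table1, cutoff = cutoff, table2 = table2,
                 table3 = table3, pvalues = pvals,
                 comparisons = comparisons, metadata = metadata)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(config$output_dir, name),
                       row.names = FALSE, na = "")
    wr(built$attrition, "attrition.csv")
    wr(cohort, "cohort_included.csv")
    wr(table1, "table1_auc.csv")
    wr(table2, "table2_characteristics.csv")
    wr(table3, "table3_outcomes.csv")
    wr(pvals, "pvalues.csv")
    wr(metadata, "run_metadata.csv")
  }
  invisible(result)
}

mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
n_pct <- function(flag) sprintf("%d (%.1f%%)", sum(flag),
                                pct(sum(flag), length(flag)))

#' Characteristics table across the four GLIM groups
#'
#' Formats demographics, severity, interventions, CRP levels and the
#' diagnosis mix as mean (SD) or n (%) for the overall cohort and each of
#' the four groups.
#'
#' @param cohort an included cohort with `four_group` assigned.
#' @return a data frame, one row per variable, one column per group.
#' @export
characteristics_table <- function(cohort) {
  groups <- c(list(overall = cohort),
              split(cohort, factor(cohort$four_group, levels = FOUR_GROUPS)))
  row_defs <- c(
    list(
      n = function(d) as.character(nrow(d)),
      age_mean_sd = function(d) mean_sd(d$age),
      male_n_pct = function(d) n_pct(d$sex == "male"),
      bmi_mean_sd = function(d) mean_sd(d$bmi),
      sofa_mean_sd = function(d) mean_sd(d$sofa_total),
      chdf_n_pct = function(d) n_pct(d$chdf),
      ihd_n_pct = function(d) n_pct(d$ihd),
      mechanical_ventilation_n_pct = function(d)
        n_pct(d$oxygen_support == "mechanical_ventilation"),
      ecmo_n_pct = function(d) n_pct(d$oxygen_support == "ecmo"),
      iabp_n_pct = function(d) n_pct(d$iabp),
      catecholamine_index_mean_sd = function(d) mean_sd(d$catecholamine_index),
      crp_day0_mean_sd = function(d) mean_sd(d$crp_day0),
      crp_max_d01_mean_sd = function(d) mean_sd(d$crp_max_d01),
      crp_max_d02_mean_sd = function(d) mean_sd(d$crp_max_d02)),
    stats::setNames(lapply(DIAGNOSIS_CATEGORIES, function(ct) {
      force(ct); function(d) n_pct(d$diagnosis_category == ct)
    }), paste0("diagnosis_", DIAGNOSIS_CATEGORIES, "_n_pct")))
  out <- data.frame(variable = names(row_defs), stringsAsFactors = FALSE)
  for (g in names(groups))
    out[[g]] <- vapply(row_defs, function(f) {
      if (nrow(groups[[g]]) == 0) "" else f(groups[[g]])
    }, character(1))
  out
}

#' Outcome table across the four GLIM groups
#'
#' n (%) for the binary outcomes and median (IQR) for BI and LOS, from a
#' [compare_four_groups()] result.
#'
#' @param comparisons result of [compare_four_groups()].
#' @return a data frame, one row per outcome, one column per group.
#' @export
outcomes_table <- function(comparisons) {
  fmt <- function(s, type) {
    if (s$n == 0) return("")
    if (type == "binary") sprintf("%d (%.1f%%)", s$count, s$pct)
    else sprintf("%g (%g, %g)", s$median, s$iqr[1], s$iqr[2])
  }
  rows <- lapply(comparisons, function(cmp) {
    vals <- vapply(FOUR_GROUPS, function(g)
      fmt(cmp$group_summaries[[g]], cmp$type), character(1))
    cbind(data.frame(outcome = cmp$outcome_name, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), stringsAsFactors = FALSE))
  })
  ns <- vapply(FOUR_GROUPS, function(g)
    comparisons[[1]]$group_summaries[[g]]$n, numeric(1))
  header <- cbind(data.frame(outcome = "n", stringsAsFactors = FALSE),
                  as.data.frame(as.list(as.character(ns)),
                                stringsAsFactors = FALSE))
  names(header) <- c("outcome", FOUR_GROUPS)
  rows <- lapply(rows, function(r) { names(r) <- c("outcome", FOUR_GROUPS); r })
  do.call(rbind, c(list(header), rows))
}

#' Long-format p-value table
#'
#' One row per omnibus test and per group pair: outcome, test, groups,
#' statistic, raw p and Bonferroni-adjusted p.
#'
#' @param comparisons result of [compare_four_groups()].
#' @return a data frame.
#' @export
pvalue_table <- function(comparisons) {
  rows <- list()
  for (cmp in comparisons) {
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = cmp$outcome_name, test = "kruskal_wallis",
      group_a = "", group_b = "",
      statistic = cmp$kw_h, p_raw = cmp$kw_p, p_adjusted = NA_real_,
      stringsAsFactors = FALSE)
    if (isTRUE(cmp$undefined)) next
    for (i in 1:3) for (j in (i + 1):4) {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = cmp$outcome_name, test = "conover",
        group_a = FOUR_GROUPS[i], group_b = FOUR_GROUPS[j],
        statistic = NA_real_,
        p_raw = cmp$pairwise[i, j],
        p_adjusted = cmp$adjusted_pairwise[i, j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
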