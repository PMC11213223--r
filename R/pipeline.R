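# Pipeline orchestration: simulate -> cohort -> screen -> characterize ->
# subgroups, with per-stage seeds derived from one master seed and plain
# delimited-text outputs for auditability.

#' Pipeline run configuration
#'
#' @param out_dir Output directory for the run's delimited-text artifacts.
#' @param sim A [sim_config()] to generate a synthetic cohort, or `NULL` when
#'   `cohort` is supplied.
#' @param cohort A [claims_cohort()] or a cohort directory path (see
#'   [read_cohort()]); ignored when `sim` is given.
#' @param outcome_codes Outcome code list data frame (default
#'   [default_outcome_codes()]).
#' @param role `"maternal"` or `"paternal"` analysis.
#' @param window_preset `"main"` or `"acute"` exposure windows.
#' @param threshold Indicator occurrence threshold (1 or 2).
#' @param restrictions Character vector of [apply_restriction()] names,
#'   applied in order.
#' @param top_k Codes retained per role for screening (default 500).
#' @param fdr_levels FDR levels reported (default 1%, 5%, 10%).
#' @param analysis_fdr FDR at which winner's-curse correction, LSA code
#'   selection and reporting operate (default 5%).
#' @param bootstrap_reps Winner's-curse bootstrap resamples (default 100).
#' @param lsa_rank Retained SVD rank (default 500, capped at the matrix
#'   rank).
#' @param cluster_cut Angular-distance cut for code grouping (default 0.4).
#' @param apriori An [apriori_config()].
#' @param subgroup_top_k Most-prevalent codes offered to the rule miner
#'   (plus the age dichotomy; default 25 keeps desk-scale mining tractable).
#' @param seed Master seed; per-stage seeds are derived deterministically so
#'   stages can be rerun independently.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, cohort = NULL,
                       outcome_codes = default_outcome_codes(),
                       role = c("maternal", "paternal"),
                       window_preset = c("main", "acute"),
                       threshold = 1L, restrictions = character(0),
                       top_k = 500L,
                       fdr_levels = c(0.01, 0.05, 0.10),
                       analysis_fdr = 0.05,
                       bootstrap_reps = 100L,
                       lsa_rank = 500L, cluster_cut = 0.4,
                       apriori = apriori_config(),
                       subgroup_top_k = 25L,
                       seed = 1L) {
  role <- match.arg(role)
  window_preset <- match.arg(window_preset)
  if (is.null(sim) && is.null(cohort)) {
    stop_config("sim/cohort", "one of them must be supplied")
  }
  structure(list(out_dir = out_dir, sim = sim, cohort = cohort,
                 outcome_codes = outcome_codes, role = role,
                 window_preset = window_preset, threshold = as.integer(threshold),
                 restrictions = restrictions, top_k = as.integer(top_k),
                 fdr_levels = fdr_levels, analysis_fdr = analysis_fdr,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 lsa_rank = as.integer(lsa_rank), cluster_cut = cluster_cut,
                 apriori = apriori, subgroup_top_k = as.integer(subgroup_top_k),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Screen the secondary (subtype) outcomes
#'
#' One screen per subtype column; subtypes with zero cases yield an
#' all-non-estimable table with an empty selection and a low-power warning
#' attribute.
#'
#' @param x Indicator matrix (or panel) shared across outcomes.
#' @param outcomes Outcome flag data frame from [flag_outcomes()].
#' @param ages Maternal ages aligned with `x` rows.
#' @param ... Passed to [screen_codes()].
#' @return Named list of `code_screen` objects (one per subtype).
#' @export
secondary_outcomes <- function(x, outcomes, ages = NULL, ...) {
  subtypes <- setdiff(names(outcomes), c("pregnancy_id", "primary"))
  out <- list()
  for (s in subtypes) {
    scr <- screen_codes(x, outcomes[[s]], ages = ages, ...)
    if (sum(outcomes[[s]]) == 0L) {
      attr(scr, "warning") <- sprintf(
        "subtype '%s' has zero cases; selection empty, power limited", s)
    }
    out[[s]] <- scr
  }
  out
}

# Serialize an hclust tree as a newick-style nested-list string.
linkage_newick <- function(tree) {
  if (is.null(tree)) return("();")
  rec <- function(i) {
    if (i < 0) return(tree$labels[-i])
    m <- tree$merge[i, ]
    sprintf("(%s,%s):%.6g", rec(m[1]), rec(m[2]), tree$height[i])
  }
  paste0(rec(nrow(tree$merge)), ";")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

screen_to_tsv <- function(scr) {
  tab <- scr$table
  tab$or <- exp(tab$log_or)
  tab$or_low <- exp(tab$ci_low)
  tab$or_high <- exp(tab$ci_high)
  if (!is.null(tab$log_or_corrected)) tab$or_corrected <- exp(tab$log_or_corrected)
  tab$items <- NULL
  tab
}

#' Run the full screening pipeline
#'
#' Orchestrates cohort acquisition (simulation or load), eligibility and
#' restrictions, father linkage, covariate-panel derivation and top-k
#' selection, primary and subtype screening with winner's-curse correction,
#' latent-semantic characterization, subgroup discovery (maternal runs), and
#' the maternal age-risk curve, writing every artifact as delimited text
#' plus a JSON run manifest.  Reruns with the same configuration and seed
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of in-memory stage results (class
#'   `pipeline_run`) with the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(package_version = as.character(packageVersion("cardioscreen")),
                   master_seed = seed,
                   stage_seeds = list(),
                   counts = list(),
                   stages = character(0))
  stage <- function(nm) {
    manifest$stages <<- c(manifest$stages, nm)
    s <- derive_seed(seed, nm)
    manifest$stage_seeds[[nm]] <<- s
    s
  }

  # ---- cohort --------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    s <- stage("simulate")
    sim <- config$sim
    sim$seed <- s
    gen <- generate_cohort(sim)
    cohort <- gen$cohort
    truth <- gen$truth
  } else {
    cohort <- if (is.character(config$cohort)) read_cohort(config$cohort) else config$cohort
  }
  stage("cohort")
  elig <- apply_eligibility(cohort)
  ids <- elig$eligible
  fathers <- link_fathers(cohort, ids)
  for (r in config$restrictions) {
    ids <- apply_restriction(cohort, ids, r, fathers = fathers)
  }
  write_tsv(elig$tally, file.path(config$out_dir, "exclusion_tally.tsv"))
  manifest$counts$pregnancies <- nrow(cohort$pregnancies)
  manifest$counts$eligible <- length(elig$eligible)
  manifest$counts$after_restrictions <- length(ids)
  manifest$counts$fathers_linked <- length(fathers)

  # ---- panels --------------------------------------------------------------
  prefix <- if (config$role == "maternal") "maternal" else "paternal"
  dxw <- window_preset(paste0(prefix, "-dx"), config$window_preset)
  rxw <- window_preset(paste0(prefix, "-rx"), config$window_preset)
  fmap <- if (config$role == "paternal") fathers else NULL
  dx_panel <- derive_panel(cohort, ids, dxw, config$threshold, fathers = fmap)
  rx_panel <- derive_panel(cohort, ids, rxw, config$threshold, fathers = fmap)
  panel_ids <- intersect(dx_panel$pregnancies, rx_panel$pregnancies)
  dx_top <- select_top_codes(dx_panel, config$top_k)
  rx_top <- select_top_codes(rx_panel, config$top_k)
  X <- cbind(dx_top$indicator[panel_ids, , drop = FALSE],
             rx_top$indicator[panel_ids, , drop = FALSE])
  counts_all <- cbind(dx_panel$counts[panel_ids, , drop = FALSE],
                      rx_panel$counts[panel_ids, , drop = FALSE])
  manifest$counts$codes_dx <- nrow(dx_top$codes)
  manifest$counts$codes_rx <- nrow(rx_top$codes)

  pg <- cohort$pregnancies
  ages <- pg$age[match(panel_ids, pg$pregnancy_id)]
  outcomes <- flag_outcomes(cohort, panel_ids, config$outcome_codes)
  y <- outcomes$primary
  manifest$counts$cases_primary <- sum(y)

  # ---- screening -----------------------------------------------------------
  s <- stage("screen")
  primary <- screen_codes(X, y, ages = ages, fdr_levels = config$fdr_levels)
  s <- stage("winners")
  primary <- correct_winners_curse(primary, fdr = config$analysis_fdr,
                                   B = config$bootstrap_reps, seed = s)
  write_tsv(screen_to_tsv(primary),
            file.path(config$out_dir, "screening_primary.tsv"))
  write_tsv(primary$table[, c("code", "signed_mlog10p", "capped")],
            file.path(config$out_dir, "manhattan.tsv"))
  subtype_screens <- secondary_outcomes(X, outcomes, ages = ages,
                                        fdr_levels = config$fdr_levels)
  for (snm in names(subtype_screens)) {
    write_tsv(screen_to_tsv(subtype_screens[[snm]]),
              file.path(config$out_dir, paste0("screening_", snm, ".tsv")))
  }

  # ---- characterization ----------------------------------------------------
  stage("lsa")
  space <- build_latent_space(counts_all, k = config$lsa_rank)
  write_tsv(data.frame(dim = seq_along(space$d), singular_value = space$d),
            file.path(config$out_dir, "singular_values.tsv"))
  vec <- data.frame(code = rownames(space$vectors), space$vectors,
                    check.names = FALSE)
  write_tsv(vec, file.path(config$out_dir, "code_vectors.tsv"))

  sel_col <- sprintf("selected_fdr%02d", round(100 * config$analysis_fdr))
  sel_codes <- primary$table$code[primary$table[[sel_col]]]
  sel_codes <- intersect(sel_codes, space$codes)
  clustering <- NULL
  sim_obj <- NULL
  if (length(sel_codes) >= 2L) {
    sim_obj <- code_cosines(space, sel_codes)
    cosm <- data.frame(code = rownames(sim_obj$cosine), sim_obj$cosine,
                       check.names = FALSE)
    write_tsv(cosm, file.path(config$out_dir, "similarity.tsv"))
    clustering <- cluster_codes(sim_obj, cut = config$cluster_cut)
    write_tsv(clustering$groups, file.path(config$out_dir, "groups.tsv"))
    writeLines(linkage_newick(clustering$tree),
               file.path(config$out_dir, "linkage.nwk"))
  } else {
    write_tsv(data.frame(code = character(0)),
              file.path(config$out_dir, "similarity.tsv"))
    write_tsv(data.frame(group = integer(0), code_terms = character(0),
                         size = integer(0)),
              file.path(config$out_dir, "groups.tsv"))
    writeLines("();", file.path(config$out_dir, "linkage.nwk"))
  }

  # ---- subgroups (maternal analysis) --------------------------------------
  subgroups <- NULL
  if (config$role == "maternal" && sum(y) > 0 && sum(y) <= sum(1 - y)) {
    s <- stage("subgroups")
    prev <- Matrix::colSums(X)
    keep <- order(-prev)[seq_len(min(config$subgroup_top_k, ncol(X)))]
    Xs <- cbind(as.matrix(X[, sort(keep), drop = FALSE]), age_features(ages))
    subgroups <- discover_subgroups(Xs, y, config$apriori, seed = s)
    rl <- subgroups$rules
    rl$items <- NULL
    write_tsv(rl, file.path(config$out_dir, "subgroup_rules.tsv"))
  } else {
    write_tsv(data.frame(antecedent = character(0)),
              file.path(config$out_dir, "subgroup_rules.tsv"))
  }

  # ---- age-risk curve ------------------------------------------------------
  stage("report")
  curve <- NULL
  if (length(unique(ages)) >= 4L && sum(y) > 0) {
    curve <- age_risk_curve(y, ages)
    write_tsv(curve$curve, file.path(config$out_dir, "age_risk_curve.tsv"))
    write_tsv(curve$bins, file.path(config$out_dir, "age_risk_bins.tsv"))
  }

  # ---- manifest ------------------------------------------------------------
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL   # hash the analysis, not its destination
  cfg_json <- jsonlite::serializeJSON(cfg_for_hash)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(list(cohort = cohort, truth = truth,
                           eligibility = elig, ids = panel_ids,
                           fathers = fathers, outcomes = outcomes,
                           primary = primary, subtypes = subtype_screens,
                           space = space, similarity = sim_obj,
                           clustering = clustering, subgroups = subgroups,
                           age_curve = curve, manifest = manifest,
                           out_dir = config$out_dir),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run ->", x$out_dir, "\n")
  cat("  eligible pregnancies:", length(x$ids), "\n")
  cat("  primary cases:", sum(x$outcomes$primary), "\n")
  sel <- grep("^selected_", names(x$primary$table), value = TRUE)
  for (cn in sel) cat(sprintf("  %s: %d\n", cn, sum(x$primary$table[[cn]])))
  if (!is.null(x$subgroups)) {
    cat("  subgroup rules selected:", sum(x$subgroups$rules$selected), "\n")
  }
  invisible(x)
}
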