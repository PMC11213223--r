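# High-risk subgroup discovery: class-balance downsampling, level-wise
# Apriori mining of outcome-consequent rules, Westfall-Young permutation
# control of the family-wise error rate, and full-data prevalence /
# risk-ratio reporting.

#' Apriori subgroup-discovery configuration
#'
#' Defaults follow the mining settings of the study: minimum support 0.1%
#' (proportion of the balanced data with the antecedent AND the outcome),
#' minimum confidence 55%, antecedents of at most 10 codes, and a 5%
#' family-wise error rate.
#'
#' @param min_support Minimum support in `(0, 1)` (default 0.001).
#' @param min_confidence Minimum confidence in `(0, 1)` (default 0.55).
#' @param max_length Maximum antecedent length (default 10).
#' @param n_perm Westfall-Young permutations (default 500; at least 100).
#' @param alpha Family-wise error rate (default 0.05).
#' @param downsample_seed Seed for the non-case downsampling.
#' @param closed_reduction Drop rules dominated by an equally-supported
#'   superset antecedent (closed-set reduction; default `FALSE`).
#' @param refit Regenerate the rule family in every permutation (the strict
#'   Westfall-Young construction; default `TRUE`).  `FALSE` keeps the
#'   observed family fixed - faster but approximate.
#' @return Object of class `apriori_config`.
#' @export
apriori_config <- function(min_support = 0.001, min_confidence = 0.55,
                           max_length = 10L, n_perm = 500L, alpha = 0.05,
                           downsample_seed = 1L, closed_reduction = FALSE,
                           refit = TRUE) {
  check_prob(min_support, "min_support", open = TRUE)
  check_prob(min_confidence, "min_confidence", open = TRUE)
  if (max_length < 1L) stop_config("max_length", "must be >= 1")
  if (alpha < 0 || alpha >= 1) stop_config("alpha", "must lie in [0, 1)")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_length = as.integer(max_length),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 downsample_seed = as.integer(downsample_seed),
                 closed_reduction = isTRUE(closed_reduction),
                 refit = isTRUE(refit)),
            class = "apriori_config")
}

#' Downsample non-cases to class balance
#'
#' Keeps every case and samples non-cases without replacement until the
#' classes are equal (50% with the outcome, 50% without).
#'
#' @param X Binary feature matrix.
#' @param y Binary outcome.
#' @param seed Integer seed (deterministic sample).
#' @return List with balanced `X` and `y`.
#' @export
downsample_balance <- function(X, y, seed = 1L) {
  y <- as.numeric(y)
  cases <- which(y == 1)
  controls <- which(y == 0)
  if (length(cases) == 0L || length(controls) == 0L) {
    stop_config("y", "needs at least one case and one non-case")
  }
  if (length(cases) > length(controls)) {
    stop_config("y", "has more cases than non-cases; cannot balance by down-sampling non-cases")
  }
  pick <- with_seed(seed, sample(controls, length(cases)))
  idx <- c(cases, pick)
  list(X = X[idx, , drop = FALSE], y = y[idx])
}

# Pearson chi-square of the antecedent-outcome 2x2 table, vectorized over
# rules: a = antecedent & outcome count, n1 = antecedent count.
chi2_stat <- function(a, n1, ncase, n) {
  b <- n1 - a
  cc <- ncase - a
  d <- n - n1 - cc
  num <- n * (a * d - b * cc)^2
  den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}

#' Mine outcome-consequent association rules (Apriori)
#'
#' Level-wise frequent-itemset generation with the anti-monotone Apriori
#' pruning, restricted to rules whose right-hand side is the outcome.
#' Support is the proportion of rows carrying the full antecedent AND the
#' outcome; confidence is the outcome rate among rows carrying the
#' antecedent.  Antecedents are kept in canonical (column-order) form, with
#' no duplicates.  Run on class-balanced data from [downsample_balance()]
#' for subgroup discovery.
#'
#' @param X Binary feature matrix with column names (include the age
#'   dichotomy from [age_features()] when emulating the published analysis).
#' @param y Binary outcome (the rule consequent).
#' @param config An [apriori_config()].
#' @return Data frame of class `subgroup_rules`: `antecedent` (codes joined
#'   by `"; "`), `items` (list of column indices), `length`, `n_antecedent`,
#'   `n_with_outcome`, `support`, `confidence`, `statistic` (the rule's 2x2
#'   chi-square).
#' @export
apriori_rules <- function(X, y, config = apriori_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (!all(X %in% c(0, 1))) stop_config("X", "must be binary (0/1)")
  if (!all(y %in% c(0, 1))) stop_config("y", "must be binary (0/1)")
  n <- nrow(X)
  ncase <- sum(y)
  min_cnt <- ceiling(config$min_support * n)
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(X)))

  ylog <- y == 1
  # level 1
  level <- list()
  for (j in seq_len(ncol(X))) {
    mask <- X[, j] == 1
    cnt_y <- sum(mask & ylog)
    if (cnt_y >= min_cnt) {
      level[[length(level) + 1L]] <- list(items = j, mask = mask,
                                          cnt_a = sum(mask), cnt_y = cnt_y)
    }
  }
  all_levels <- list(level)
  len <- 1L
  while (length(level) > 1L && len < config$max_length) {
    keys <- vapply(level, function(r) paste(r$items, collapse = ","), character(1))
    keyset <- new.env(hash = TRUE)
    for (k in keys) assign(k, TRUE, envir = keyset)
    nxt <- list()
    # join itemsets sharing their first len-1 items
    prefixes <- vapply(level, function(r) paste(r$items[-len], collapse = ","), character(1))
    ord <- order(prefixes)
    level <- level[ord]
    prefixes <- prefixes[ord]
    i <- 1L
    while (i <= length(level)) {
      j_end <- i
      while (j_end < length(level) && prefixes[j_end + 1L] == prefixes[i]) j_end <- j_end + 1L
      if (j_end > i) {
        for (p in i:(j_end - 1L)) {
          for (q in (p + 1L):j_end) {
            items <- sort(c(level[[p]]$items, level[[q]]$items[len]))
            # anti-monotone pruning: all (len)-subsets must be frequent
            ok <- TRUE
            for (drop in seq_along(items)) {
              if (!exists(paste(items[-drop], collapse = ","), envir = keyset,
                          inherits = FALSE)) {
                ok <- FALSE
                break
              }
            }
            if (!ok) next
            mask <- level[[p]]$mask & X[, level[[q]]$items[len]] == 1
            cnt_y <- sum(mask & ylog)
            if (cnt_y >= min_cnt) {
              nxt[[length(nxt) + 1L]] <- list(items = items, mask = mask,
                                              cnt_a = sum(mask), cnt_y = cnt_y)
            }
          }
        }
      }
      i <- j_end + 1L
    }
    level <- nxt
    len <- len + 1L
    if (length(level)) all_levels[[len]] <- level
  }

  rules <- unlist(all_levels, recursive = FALSE)
  if (length(rules) == 0L) {
    out <- data.frame(antecedent = character(0), length = integer(0),
                      n_antecedent = integer(0), n_with_outcome = integer(0),
                      support = numeric(0), confidence = numeric(0),
                      statistic = numeric(0), stringsAsFactors = FALSE)
    out$items <- list()
  } else {
    conf <- vapply(rules, function(r) r$cnt_y / r$cnt_a, numeric(1))
    keep <- conf >= config$min_confidence
    rules <- rules[keep]
    conf <- conf[keep]
    out <- data.frame(
      antecedent = vapply(rules, function(r) paste(feats[r$items], collapse = "; "),
                          character(1)),
      length = vapply(rules, function(r) length(r$items), integer(1)),
      n_antecedent = vapply(rules, function(r) r$cnt_a, numeric(1)),
      n_with_outcome = vapply(rules, function(r) r$cnt_y, numeric(1)),
      support = vapply(rules, function(r) r$cnt_y / n, numeric(1)),
      confidence = conf,
      stringsAsFactors = FALSE)
    out$statistic <- chi2_stat(out$n_with_outcome, out$n_antecedent, ncase, n)
    out$items <- lapply(rules, `[[`, "items")
    if (config$closed_reduction && nrow(out) > 1L) {
      # closed-set reduction: drop a rule when a strict superset antecedent
      # has identical antecedent support
      drop <- logical(nrow(out))
      for (p in seq_len(nrow(out))) {
        for (q in seq_len(nrow(out))) {
          if (p == q || out$length[q] <= out$length[p]) next
          if (all(out$items[[p]] %in% out$items[[q]]) &&
              out$n_antecedent[q] == out$n_antecedent[p]) {
            drop[p] <- TRUE
            break
          }
        }
      }
      out <- out[!drop, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "n") <- n
  attr(out, "n_cases") <- ncase
  attr(out, "features") <- feats
  class(out) <- c("subgroup_rules", "data.frame")
  out
}

#' Age dichotomy features
#'
#' The subgroup analysis categorizes maternal age at 35 years; both sides of
#' the cut are offered as binary features so either can enter an antecedent.
#'
#' @param ages Ages in years.
#' @param cut Dichotomy point (default 35).
#' @return Matrix with columns `age_lt_<cut>` and `age_ge_<cut>`.
#' @export
age_features <- function(ages, cut = 35) {
  m <- cbind(as.integer(ages < cut), as.integer(ages >= cut))
  colnames(m) <- paste0(c("age_lt_", "age_ge_"), cut)
  m
}

#' Westfall-Young permutation selection of rules
#'
#' Controls the family-wise error rate by comparing each rule's observed
#' chi-square statistic with the permutation distribution of the maximum
#' statistic over the rule family: the outcome is permuted, the family is
#' re-mined under identical thresholds (strict mode), and each rule's
#' adjusted p is the fraction of permutations whose family maximum reaches
#' its observed statistic.  The family maximum also covers the observed
#' antecedents themselves, so adjusted p-values dominate the per-rule
#' (unadjusted) permutation p-values.
#'
#' @param rules A [apriori_rules()] result.
#' @param X,y The (balanced) data the rules were mined on.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Family-wise error rate; `alpha = 0` selects nothing.
#' @param seed Integer seed.
#' @param config Mining configuration (defaults to the one attached to
#'   `rules`); its `refit` flag switches strict re-mining on or off.
#' @return `rules` with columns `p_unadjusted`, `p_wy`, `selected` added.
#' @export
westfall_young <- function(rules, X, y, n_perm = 500L, alpha = 0.05,
                           seed = 1L, config = attr(rules, "config")) {
  stopifnot(inherits(rules, "subgroup_rules"))
  if (n_perm < 100L) stop_config("n_perm", "must be >= 100")
  if (nrow(rules) == 0L) {
    rules$p_unadjusted <- numeric(0)
    rules$p_wy <- numeric(0)
    rules$selected <- logical(0)
    return(rules)
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  ncase <- sum(y)
  R <- nrow(rules)
  # antecedent row-masks, one column per rule
  M <- vapply(rules$items, function(it) {
    as.numeric(rowSums(X[, it, drop = FALSE]) == length(it))
  }, numeric(n))
  n1 <- rules$n_antecedent
  obs <- rules$statistic

  exceed_r <- numeric(R)
  exceed_max <- numeric(R)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      a <- as.numeric(crossprod(M, yp))
      stat_r <- chi2_stat(a, n1, ncase, n)
      fam_max <- max(stat_r)
      if (isTRUE(config$refit)) {
        mined <- apriori_rules(X, yp, config)
        if (nrow(mined)) fam_max <- max(fam_max, max(mined$statistic))
      }
      exceed_r <- exceed_r + (stat_r >= obs)
      exceed_max <- exceed_max + (fam_max >= obs)
    }
  })
  rules$p_unadjusted <- exceed_r / n_perm
  rules$p_wy <- exceed_max / n_perm
  rules$selected <- if (alpha > 0) rules$p_wy <= alpha else rep(FALSE, R)
  rules
}

#' Full-data subgroup metrics
#'
#' Prevalence of the antecedent, and the risk ratio of the outcome between
#' antecedent carriers and non-carriers, in the complete (un-downsampled)
#' data, with a Katz log-normal 95% confidence interval.  When the 2x2 table
#' has a zero cell, 0.5 is added to all cells (continuity correction) and the
#' result is flagged; an empty in-group or out-group yields an undefined,
#' flagged risk ratio.
#'
#' @param items Antecedent column indices (or a single row of a
#'   `subgroup_rules` table via its `items` element).
#' @param X_full Full binary feature matrix.
#' @param y_full Full binary outcome.
#' @return List: `prevalence`, `rr`, `rr_low`, `rr_high`,
#'   `continuity_corrected`, `undefined`.
#' @export
subgroup_metrics <- function(items, X_full, y_full) {
  X_full <- as.matrix(X_full)
  y_full <- as.numeric(y_full)
  inb <- rowSums(X_full[, items, drop = FALSE]) == length(items)
  n1 <- sum(inb)
  n0 <- sum(!inb)
  prevalence <- n1 / length(y_full)
  if (n1 == 0L || n0 == 0L) {
    return(list(prevalence = prevalence, rr = NA_real_, rr_low = NA_real_,
                rr_high = NA_real_, continuity_corrected = FALSE,
                undefined = TRUE))
  }
  a <- sum(y_full[inb])
  cc <- sum(y_full[!inb])
  corrected <- any(c(a, n1 - a, cc, n0 - cc) == 0)
  if (corrected) {
    a <- a + 0.5
    cc <- cc + 0.5
    n1 <- n1 + 1
    n0 <- n0 + 1
  }
  rr <- (a / n1) / (cc / n0)
  se <- sqrt(1 / a - 1 / n1 + 1 / cc - 1 / n0)
  z <- qnorm(0.975)
  list(prevalence = prevalence, rr = rr,
       rr_low = rr * exp(-z * se), rr_high = rr * exp(z * se),
       continuity_corrected = corrected, undefined = FALSE)
}

#' Discover high-risk subgroups end to end
#'
#' Downsamples non-cases to class balance, mines outcome-consequent rules,
#' applies Westfall-Young selection, and reports each rule's prevalence and
#' risk ratio in the full data.
#'
#' @param X Full binary feature matrix (include [age_features()] columns for
#'   the published age dichotomy).
#' @param y Full binary outcome.
#' @param config An [apriori_config()].
#' @param seed Master seed for downsampling and permutation.
#' @return Object of class `subgroup_discovery`: the rule table augmented
#'   with `prevalence_pct`, `rr`, `rr_low`, `rr_high`, `p_wy`, `selected`.
#' @export
discover_subgroups <- function(X, y, config = apriori_config(), seed = 1L) {
  bal <- downsample_balance(X, y, seed = config$downsample_seed + seed)
  rules <- apriori_rules(bal$X, bal$y, config)
  rules <- westfall_young(rules, bal$X, bal$y, n_perm = config$n_perm,
                          alpha = config$alpha, seed = seed + 1L,
                          config = config)
  if (nrow(rules)) {
    met <- lapply(rules$items, subgroup_metrics, X_full = X, y_full = y)
    rules$prevalence_pct <- 100 * vapply(met, `[[`, numeric(1), "prevalence")
    rules$rr <- vapply(met, `[[`, numeric(1), "rr")
    rules$rr_low <- vapply(met, `[[`, numeric(1), "rr_low")
    rules$rr_high <- vapply(met, `[[`, numeric(1), "rr_high")
    rules$rr_flagged <- vapply(met, function(m) m$continuity_corrected || m$undefined,
                               logical(1))
  } else {
    rules$prevalence_pct <- numeric(0)
    rules$rr <- numeric(0)
    rules$rr_low <- numeric(0)
    rules$rr_high <- numeric(0)
    rules$rr_flagged <- logical(0)
  }
  structure(list(rules = rules, config = config, seed = seed,
                 n = length(y), n_cases = sum(y)),
            class = "subgroup_discovery")
}

#' @export
print.subgroup_discovery <- function(x, ...) {
  cat(sprintf("Subgroup discovery: %d rules mined, %d selected at %.0f%% FWER\n",
              nrow(x$rules), sum(x$rules$selected), 100 * x$config$alpha))
  sel <- x$rules[x$rules$selected, , drop = FALSE]
  if (nrow(sel)) {
    df <- data.frame(
      Rule = sel$antecedent,
      `Prevalence (%)` = sprintf("%.1f", sel$prevalence_pct),
      `Risk ratio (95% CI)` = sprintf("%.2f (%.2f-%.2f)",
                                      sel$rr, sel$rr_low, sel$rr_high),
      check.names = FALSE)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
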