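# Mass univariate logistic screening with spline age adjustment,
# likelihood-ratio tests, BH-FDR selection, winner's-curse bootstrap
# correction, and signed-Manhattan output.

# Internal: one IRLS logistic fit on a dense design matrix.
fit_logit <- function(X, y, start = NULL, tol = 1e-9, maxit = 30L) {
  if (is.null(start)) start <- numeric(ncol(X))
  irls_logit(X, y, start, tol, maxit)
}

#' Fit one per-code logistic model
#'
#' Maximizes the binomial likelihood for
#' `logit P(y = 1) = b0 + b1 x + spline(age)` and tests `b1 = 0` with a
#' 1-df likelihood-ratio test against the reduced model omitting `x`.
#' Codes with an empty cell in the exposure-outcome 2x2 table (zero exposed,
#' zero exposed cases, no unexposed cases, ...) or a non-converged fit are
#' returned with status `"non-estimable"` and p-value 1, keeping them out of
#' selection and out of the bias correction.
#'
#' @param y Binary outcome vector.
#' @param x Binary exposure indicator.
#' @param age_design Optional spline design matrix from [rcs_basis()]
#'   (`NULL` for an intercept-only adjustment set).
#' @param reduced Optional precomputed reduced-model fit (shared across codes
#'   in a screen).
#' @return List of class `code_fit`: `log_or`, `se`, `ci_low`, `ci_high`,
#'   `lrt`, `p_value`, `n_exposed`, `n_exposed_cases`, `status`.
#' @export
fit_code_model <- function(y, x, age_design = NULL, reduced = NULL) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  stopifnot(length(y) == length(x))
  n <- length(y)
  n_exposed <- sum(x)
  n_exposed_cases <- sum(x * y)
  a <- n_exposed_cases
  b <- n_exposed - a
  cc <- sum(y) - a
  d <- n - n_exposed - cc

  out <- list(log_or = NA_real_, se = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, lrt = NA_real_, p_value = 1,
              n_exposed = n_exposed, n_exposed_cases = n_exposed_cases,
              status = "non-estimable")
  class(out) <- "code_fit"
  if (min(a, b, cc, d) == 0) return(out)

  ones <- rep(1, n)
  Xr <- cbind(ones, age_design)
  if (is.null(reduced)) reduced <- fit_logit(Xr, y)
  Xf <- cbind(ones, x, age_design)
  k <- ncol(Xr)
  start <- c(reduced$coefficients[1L], 0,
             if (k > 1L) reduced$coefficients[2:k])
  fit <- fit_logit(Xf, y, start = start)
  beta1 <- fit$coefficients[2L]
  se1 <- fit$se[2L]
  if (!fit$converged || !is.finite(se1) || abs(beta1) > 15) return(out)

  lrt <- max(0, reduced$deviance - fit$deviance)
  out$log_or <- beta1
  out$se <- se1
  out$ci_low <- beta1 - qnorm(0.975) * se1
  out$ci_high <- beta1 + qnorm(0.975) * se1
  out$lrt <- lrt
  out$p_value <- pchisq(lrt, df = 1L, lower.tail = FALSE)
  out$status <- "ok"
  out
}

#' Benjamini-Hochberg selection
#'
#' Step-up FDR control: adjusted `p_(i) = min_{j >= i} m p_(j) / j` capped at
#' 1; codes with adjusted p at or below `q` are selected.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)`.
#' @return List with `adjusted` and logical `selected`.
#' @export
bh_select <- function(pvals, q) {
  if (length(pvals) == 0L) return(list(adjusted = numeric(0), selected = logical(0)))
  check_prob(pvals, "pvals")
  if (!is.numeric(q) || q <= 0 || q >= 1) stop_config("q", "must lie in (0, 1)")
  adjusted <- p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, selected = adjusted <= q)
}

#' Signed -log10 p-values for the Manhattan plot
#'
#' `-log10(p)` multiplied by the sign of the log odds ratio, so positive and
#' negative associations point in opposite directions.  Values beyond `cap`
#' (including p-value underflow to 0) are capped and flagged; the cap is a
#' display convention, the screening table keeps the raw p-value.
#'
#' @param p P-values.
#' @param log_or Log odds-ratio estimates (zero gives a signed value of 0).
#' @param cap Cap on `-log10(p)` (default 20).
#' @return Data frame with `signed_mlog10p` and logical `capped`.
#' @export
signed_log10 <- function(p, log_or, cap = 20) {
  v <- -log10(p)
  over <- !is.finite(v) | v > cap
  v[over] <- cap
  s <- sign(log_or)
  s[is.na(s)] <- 0
  data.frame(signed_mlog10p = v * s, capped = over)
}

#' Screen every code against the outcome
#'
#' The package's central fit: a separate age-adjusted logistic model per
#' code, likelihood-ratio p-values, and Benjamini-Hochberg selection at each
#' FDR level.  All codes passed in one call form one BH family (screen
#' maternal and paternal panels, and diagnosis/medication roles, in separate
#' calls to keep separate families, or pool them in one call).
#'
#' @param x Binary indicator matrix (pregnancies x codes; base or
#'   `Matrix` sparse) with column names, or a [derive_panel()] panel.
#' @param y Binary outcome vector.
#' @param ages Maternal ages (years); `NULL` for unadjusted screening.
#' @param n_knots Spline knots for the age adjustment (default 4).
#' @param fdr_levels FDR levels for selection flags
#'   (default `c(0.01, 0.05, 0.10)`).
#' @return Object of class `code_screen` with a `table` data frame (one row
#'   per code) and `print`, `summary`, `coef`, `plot` methods.
#' @export
screen_codes <- function(x, y, ages = NULL, n_knots = 4L,
                         fdr_levels = c(0.01, 0.05, 0.10)) {
  if (inherits(x, "covariate_panel")) x <- x$indicator
  if (is.null(colnames(x))) colnames(x) <- paste0("code", seq_len(ncol(x)))
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))

  basis <- NULL
  age_design <- NULL
  if (!is.null(ages) && length(unique(ages)) >= n_knots) {
    basis <- rcs_basis(ages, n_knots)
    age_design <- basis$design
  }
  degenerate <- sum(y) == 0 || sum(y) == length(y)
  reduced <- if (!degenerate) fit_logit(cbind(rep(1, length(y)), age_design), y)

  m <- ncol(x)
  fits <- vector("list", m)
  for (j in seq_len(m)) {
    fits[[j]] <- fit_code_model(y, as.numeric(x[, j]), age_design, reduced)
  }
  tab <- data.frame(
    code = colnames(x),
    n_exposed = vapply(fits, `[[`, numeric(1), "n_exposed"),
    n_exposed_cases = vapply(fits, `[[`, numeric(1), "n_exposed_cases"),
    log_or = vapply(fits, `[[`, numeric(1), "log_or"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    ci_low = vapply(fits, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(fits, `[[`, numeric(1), "ci_high"),
    lrt = vapply(fits, `[[`, numeric(1), "lrt"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    status = vapply(fits, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  bh <- bh_select(tab$p_value, max(fdr_levels))
  tab$p_adjusted <- bh$adjusted
  for (q in fdr_levels) {
    tab[[sprintf("selected_fdr%02d", round(100 * q))]] <- tab$p_adjusted <= q
  }
  sl <- signed_log10(tab$p_value, tab$log_or)
  tab$signed_mlog10p <- sl$signed_mlog10p
  tab$capped <- sl$capped

  structure(list(table = tab, basis = basis, reduced = reduced,
                 x = x, y = y, ages = ages, fdr_levels = fdr_levels,
                 n = length(y), call = match.call()),
            class = "code_screen")
}

#' @export
print.code_screen <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Code screen: %d codes, %d pregnancies, %d cases\n",
              nrow(tab), x$n, sum(x$y)))
  if (!is.null(x$basis)) {
    cat("  age adjustment: restricted cubic spline,",
        x$basis$n_knots, "knots\n")
  } else {
    cat("  age adjustment: none\n")
  }
  for (q in x$fdr_levels) {
    col <- sprintf("selected_fdr%02d", round(100 * q))
    cat(sprintf("  selected at %2.0f%% FDR: %d\n", 100 * q, sum(tab[[col]])))
  }
  ne <- sum(tab$status != "ok")
  if (ne) cat("  non-estimable codes:", ne, "\n")
  invisible(x)
}

#' @export
summary.code_screen <- function(object, fdr = 0.05, ...) {
  tab <- object$table
  col <- sprintf("selected_fdr%02d", round(100 * fdr))
  if (!col %in% names(tab)) col <- "selected_fdr05"
  sel <- tab[tab[[col]], , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  out <- sel[, c("code", "n_exposed", "n_exposed_cases", "log_or",
                 "ci_low", "ci_high", "p_value", "p_adjusted")]
  out$or <- exp(out$log_or)
  structure(list(selected = out, fdr = fdr, n_codes = nrow(tab)),
            class = "summary.code_screen")
}

#' @export
print.summary.code_screen <- function(x, ...) {
  cat(sprintf("%d of %d codes selected at %.0f%% FDR\n",
              nrow(x$selected), x$n_codes, 100 * x$fdr))
  if (nrow(x$selected)) {
    df <- x$selected
    df$or <- sprintf("%.2f (%.2f-%.2f)", exp(df$log_or),
                     exp(df$ci_low), exp(df$ci_high))
    print(df[, c("code", "n_exposed_cases", "or", "p_value", "p_adjusted")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.code_screen <- function(object, ...) {
  stats::setNames(object$table$log_or, object$table$code)
}

#' Signed Manhattan plot of a code screen
#'
#' @param x A `code_screen`.
#' @param fdr FDR level whose selection threshold line is drawn.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.code_screen <- function(x, fdr = 0.05, ...) {
  tab <- x$table
  col <- sprintf("selected_fdr%02d", round(100 * fdr))
  sel <- if (col %in% names(tab)) tab[[col]] else FALSE
  plot(seq_len(nrow(tab)), tab$signed_mlog10p,
       pch = ifelse(tab$capped, 8, ifelse(sel, 19, 1)),
       col = ifelse(sel, "firebrick", "grey40"),
       xlab = "code rank", ylab = "signed -log10 p", ...)
  abline(h = 0, col = "grey70")
  invisible(x)
}

#' Winner's-curse bias correction by conditional bootstrap
#'
#' Effect estimates selected by multiplicity-corrected screening are biased
#' away from the null (the winner's curse).  The correction resamples
#' pregnancies with replacement, reruns the full per-code fit and BH
#' selection in each resample, and, for each originally selected code,
#' estimates the selection bias as the mean over resamples *in which the code
#' was again selected* of (bootstrap log-OR minus full-data log-OR); the
#' corrected estimate subtracts this bias.  Codes never re-selected in any
#' resample get a missing correction and are flagged.
#'
#' @param object A [screen_codes()] fit.
#' @param fdr Analysis FDR at which selection (and re-selection) operates.
#' @param B Number of bootstrap resamples (>= 50).
#' @param seed Integer seed (resampling is deterministic given the seed).
#' @return The `code_screen` with table columns `bias`, `log_or_corrected`,
#'   `n_boot_selected`, and `never_reselected` added for selected codes.
#' @export
correct_winners_curse <- function(object, fdr = 0.05, B = 200L, seed = 1L) {
  stopifnot(inherits(object, "code_screen"))
  if (B < 50L) stop_config("B", "must be >= 50 (bias estimate is unstable below that)")
  tab <- object$table
  sel_idx <- which(tab$p_adjusted <= fdr & tab$status == "ok")
  tab$bias <- NA_real_
  tab$log_or_corrected <- NA_real_
  tab$n_boot_selected <- NA_integer_
  tab$never_reselected <- FALSE
  if (length(sel_idx) == 0L) {
    object$table <- tab
    object$winners_curse <- list(fdr = fdr, B = B, seed = seed, selected = integer(0))
    return(object)
  }
  x <- object$x
  y <- object$y
  n <- length(y)
  m <- ncol(x)
  boot_sum <- numeric(length(sel_idx))
  boot_n <- integer(length(sel_idx))

  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      ab <- if (is.null(object$basis)) NULL else object$basis$design[idx, , drop = FALSE]
      reduced_b <- fit_logit(cbind(rep(1, n), ab), yb)
      pb <- numeric(m)
      lb <- numeric(m)
      okb <- logical(m)
      xb <- x[idx, , drop = FALSE]
      for (j in seq_len(m)) {
        f <- fit_code_model(yb, as.numeric(xb[, j]), ab, reduced_b)
        pb[j] <- f$p_value
        lb[j] <- f$log_or
        okb[j] <- f$status == "ok"
      }
      selected_b <- bh_select(pb, fdr)$selected & okb
      hit <- which(sel_idx %in% which(selected_b))
      if (length(hit)) {
        boot_sum[hit] <- boot_sum[hit] + lb[sel_idx[hit]]
        boot_n[hit] <- boot_n[hit] + 1L
      }
    }
  })

  bias <- ifelse(boot_n > 0L, boot_sum / boot_n - tab$log_or[sel_idx], NA_real_)
  tab$bias[sel_idx] <- bias
  tab$log_or_corrected[sel_idx] <- tab$log_or[sel_idx] - bias
  tab$n_boot_selected[sel_idx] <- boot_n
  tab$never_reselected[sel_idx] <- boot_n == 0L
  object$table <- tab
  object$winners_curse <- list(fdr = fdr, B = B, seed = seed,
                               selected = sel_idx,
                               scheme = "conditional bootstrap (resample, refit, reselect)")
  object
}

#' Maternal age-risk curve
#'
#' Fits a logistic model of the outcome on a restricted cubic spline of
#' maternal age and returns the predicted risk over an age grid, together
#' with observed risks in 2-year age bins containing more than `min_bin`
#' pregnancies.
#'
#' @param y Binary outcome.
#' @param ages Maternal ages in years.
#' @param grid Ages at which to predict (default: integer grid over the
#'   observed range); grid points outside the observed range are flagged as
#'   extrapolated.
#' @param n_knots Spline knots (default 4).
#' @param bin_width Width of the observed-risk bins in years (default 2).
#' @param min_bin Minimum pregnancies for a bin to be reported (default 100;
#'   bins must exceed this count).
#' @return Object of class `age_risk_curve`: `curve` (age, risk,
#'   extrapolated), `bins` (age_mid, n, risk), `coefficients`, `basis`.
#' @export
age_risk_curve <- function(y, ages, grid = NULL, n_knots = 4L,
                           bin_width = 2, min_bin = 100L) {
  y <- as.numeric(y)
  basis <- rcs_basis(ages, n_knots)
  fit <- fit_logit(cbind(rep(1, length(y)), basis$design), y)
  if (is.null(grid)) grid <- seq(floor(min(ages)), ceiling(max(ages)))
  risk <- as.numeric(plogis(cbind(1, predict(basis, grid)) %*% fit$coefficients))
  curve <- data.frame(age = grid, risk = risk,
                      extrapolated = grid < basis$range[1] | grid > basis$range[2])
  lo <- floor(min(ages) / bin_width) * bin_width
  mid <- lo + floor((ages - lo) / bin_width) * bin_width + bin_width / 2
  nb <- tapply(y, mid, length)
  rb <- tapply(y, mid, mean)
  keep <- nb > min_bin
  bins <- data.frame(age_mid = as.numeric(names(nb))[keep],
                     n = as.integer(nb[keep]), risk = as.numeric(rb[keep]))
  structure(list(curve = curve, bins = bins,
                 coefficients = fit$coefficients, basis = basis),
            class = "age_risk_curve")
}

#' @export
plot.age_risk_curve <- function(x, ...) {
  plot(x$curve$age, x$curve$risk, type = "l",
       xlab = "maternal age (years)", ylab = "predicted risk", ...)
  if (nrow(x$bins)) points(x$bins$age_mid, x$bins$risk, pch = 1)
  invisible(x)
}

#' @importFrom stats qnorm
NULL
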