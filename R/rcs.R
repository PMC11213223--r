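# Restricted cubic spline basis for maternal-age adjustment.

# Standard quantile placements for k knots (outer knots at the 5th/95th
# percentiles for k >= 4).
rcs_knot_probs <- function(k) {
  switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    seq(0.05, 0.95, length.out = k))
}

#' Restricted cubic spline basis
#'
#' Natural cubic spline basis with `n_knots` knots at the standard quantiles
#' of the observed ages (5/35/65/95th percentiles for the default 4 knots).
#' The basis is linear beyond the boundary knots and has continuous first and
#' second derivatives everywhere; its dimension is `n_knots - 1`
#' (including the implicit linear term).
#'
#' @param ages Numeric vector of ages in years.
#' @param n_knots Number of knots (>= 3; default 4).
#' @return Object of class `rcs_basis` with elements `knots`, `design`
#'   (the n x (n_knots - 1) basis matrix), and a `predict` method for new
#'   ages.
#' @export
rcs_basis <- function(ages, n_knots = 4L) {
  if (n_knots < 3L) stop_config("n_knots", "must be >= 3")
  if (length(unique(ages)) < n_knots) {
    stop(sprintf(paste("only %d distinct age values for %d knots;",
                       "reduce n_knots"), length(unique(ages)), n_knots),
         call. = FALSE)
  }
  knots <- unname(quantile(ages, rcs_knot_probs(n_knots), type = 7))
  if (anyDuplicated(knots)) {
    stop("duplicate knot locations; reduce n_knots", call. = FALSE)
  }
  ns_obj <- splines::ns(ages, knots = knots[-c(1L, n_knots)],
                        Boundary.knots = knots[c(1L, n_knots)])
  design <- matrix(as.numeric(ns_obj), nrow = length(ages))
  colnames(design) <- paste0("rcs", seq_len(ncol(design)))
  structure(list(knots = knots, n_knots = n_knots, ns = ns_obj,
                 design = design, range = range(ages)),
            class = "rcs_basis")
}

#' @rdname rcs_basis
#' @param object An `rcs_basis`.
#' @param newages Ages at which to evaluate the basis.
#' @param ... Unused.
#' @export
predict.rcs_basis <- function(object, newages, ...) {
  m <- stats::predict(object$ns, newages)
  m <- matrix(as.numeric(m), nrow = length(newages))
  colnames(m) <- paste0("rcs", seq_len(ncol(m)))
  m
}

#' @export
print.rcs_basis <- function(x, ...) {
  cat("Restricted cubic spline basis:", x$n_knots, "knots at",
      paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
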