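# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derived from a master seed; kept below 2^31.
derive_seed <- function(master, stage) {
  stages <- c(simulate = 1L, cohort = 2L, screen = 3L, winners = 4L,
              lsa = 5L, subgroups = 6L, report = 7L)
  idx <- stages[[stage]]
  as.integer((as.double(master) * 48271 + idx * 16807) %% 2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open = FALSE) {
  if (!is.numeric(x) || anyNA(x) ||
      any(x < 0) || any(x > 1) ||
      (open && any(x == 0 | x == 1))) {
    stop_config(field, if (open) "must be strictly inside (0, 1)"
                else "must be a probability in [0, 1]")
  }
  invisible(x)
}

# Merge enrollment spans per person (inclusive integer days; spans touching on
# adjacent days join).  With spans sorted by (person, start), the running max
# of end-days within person is the coverage frontier; a merged span begins
# where a start-day jumps past frontier + 1.
merge_spans <- function(spans) {
  if (nrow(spans) == 0L) {
    return(data.frame(person_id = character(), start_day = integer(),
                      end_day = integer(), stringsAsFactors = FALSE))
  }
  ord <- order(spans$person_id, spans$start_day, spans$end_day)
  pid <- as.character(spans$person_id[ord])
  s <- as.integer(spans$start_day[ord])
  e <- as.integer(spans$end_day[ord])
  rmax <- stats::ave(e, pid, FUN = cummax)
  n <- length(pid)
  first <- c(TRUE, pid[-1L] != pid[-n])
  gap <- c(TRUE, s[-1L] > rmax[-n] + 1L)
  brk <- first | gap
  last <- c(brk[-1L], TRUE)
  data.frame(person_id = pid[brk], start_day = s[brk], end_day = rmax[last],
             stringsAsFactors = FALSE)
}

# Is each query window [from, to] continuously covered for `person`?
spans_cover <- function(spans, person, from, to) {
  stopifnot(length(person) == length(from), length(from) == length(to))
  if (length(person) == 0L) return(logical(0))
  merged <- merge_spans(spans)
  q <- data.frame(.q = seq_along(person), person_id = as.character(person),
                  from = from, to = to, stringsAsFactors = FALSE)
  j <- merge(q, merged, by = "person_id")
  out <- logical(length(person))
  if (nrow(j)) {
    ok <- j$start_day <= j$from & j$end_day >= j$to
    hit <- unique(j$.q[ok])
    out[hit] <- TRUE
  }
  out
}
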