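#' Encode a cohort of patient records into numeric matrices
#'
#' Turns a record table (one row per patient; covariate columns may contain
#' `NA` for missing entries) into the numeric form the network consumes:
#' a covariate matrix `X`, a binary missingness-indicator matrix `R`
#' (`R[i, j] = 0` marks a missing entry), a time vector `t` and an event
#' vector `s`. Continuous covariates are standardized to zero mean and unit
#' scale using the observed entries only (sample standard deviation, n - 1
#' denominator); categorical covariates are mapped through the schema's code
#' map. Missing entries are then zero-filled, so `X * (1 - R) == 0` always
#' holds and zero is unambiguously "missing" (all category codes are
#' nonzero).
#'
#' @param records a data.frame with columns `id`, one column per schema
#'   covariate (same names), `time` (positive, months) and `event` (0/1).
#' @param schema a [cohort_schema()].
#' @param stats optional standardization statistics from a previous (training)
#'   call; when supplied they are reused verbatim so validation and test
#'   cohorts are encoded on the training scale. When `NULL`, statistics are
#'   computed from the observed values of `records`.
#' @param standardize logical; set `FALSE` to pass continuous covariates
#'   through unscaled.
#' @return an object of class `encoded_cohort`: list with elements `X`, `R`,
#'   `time`, `event`, `ids`, `stats`, `schema`.
#' @export
encode_cohort <- function(records, schema, stats = NULL, standardize = TRUE) {
  stopifnot(inherits(schema, "cohort_schema"), is.data.frame(records))
  need <- c("id", schema_names(schema), "time", "event")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop_survnet("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(records)
  p <- schema_p(schema)
  if (n < 1) stop_survnet("empty cohort")
  time <- as.numeric(records$time)
  event <- as.numeric(records$event)
  if (anyNA(time) || anyNA(event)) {
    stop_survnet("records with missing time or event must be dropped before encoding ",
                 "(read_cohort does this)")
  }
  if (any(time <= 0)) stop_survnet("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop_survnet("event indicator must be 0 or 1")

  X <- matrix(0, n, p, dimnames = list(NULL, schema_names(schema)))
  R <- matrix(1, n, p, dimnames = list(NULL, schema_names(schema)))
  compute_stats <- is.null(stats)
  if (compute_stats) stats <- list()

  for (j in seq_len(p)) {
    cv <- schema$covariates[[j]]
    col <- records[[cv$name]]
    if (cv$kind == "continuous") {
      v <- as.numeric(col)
      obs <- !is.na(v)
      if (standardize) {
        if (compute_stats) {
          if (!any(obs)) {
            stop_survnet("covariate '", cv$name,
                         "': no observed values to compute standardization statistics")
          }
          mu <- mean(v[obs])
          sdv <- stats::sd(v[obs])
          if (!is.finite(sdv) || sdv == 0) sdv <- 1  # degenerate column: center only
          stats[[cv$name]] <- list(center = mu, scale = sdv)
        }
        st <- stats[[cv$name]]
        if (is.null(st)) {
          stop_survnet("supplied stats lack entry for continuous covariate '", cv$name, "'")
        }
        v <- (v - st$center) / st$scale
      }
      X[obs, j] <- v[obs]
      R[!obs, j] <- 0
    } else {
      lab <- as.character(col)
      obs <- !is.na(lab) & nzchar(lab)
      bad <- obs & !(lab %in% names(cv$codes))
      if (any(bad)) {
        stop_survnet("covariate '", cv$name, "': unknown category label '",
                     lab[which(bad)[1]], "'")
      }
      X[obs, j] <- unname(cv$codes[lab[obs]])
      R[!obs, j] <- 0
    }
  }
  structure(
    list(X = X, R = R, time = time, event = event,
         ids = as.character(records$id), stats = stats, schema = schema),
    class = "encoded_cohort"
  )
}

#' @export
print.encoded_cohort <- function(x, ...) {
  cat("encoded_cohort: n =", nrow(x$X), " p =", ncol(x$X),
      " events =", sum(x$event),
      " missing entries =", sum(x$R == 0), "\n")
  invisible(x)
}

#' Decode an encoded cohort back to patient records
#'
#' Inverse of [encode_cohort()]: continuous covariates are unscaled with the
#' stored statistics, categorical codes are mapped back to labels, and masked
#' entries become `NA`. Re-encoding the result with the same schema and stats
#' reproduces `X` and `R` exactly.
#'
#' @param cohort an `encoded_cohort`.
#' @return a record data.frame.
#' @export
decode_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "encoded_cohort"))
  schema <- cohort$schema
  out <- data.frame(id = cohort$ids, stringsAsFactors = FALSE)
  for (j in seq_len(schema_p(schema))) {
    cv <- schema$covariates[[j]]
    x <- cohort$X[, j]
    r <- cohort$R[, j]
    if (cv$kind == "continuous") {
      st <- cohort$stats[[cv$name]]
      v <- if (is.null(st)) x else x * st$scale + st$center
      v[r == 0] <- NA_real_
      out[[cv$name]] <- v
    } else {
      lab <- names(cv$codes)[match(x, cv$codes)]
      lab[r == 0] <- NA_character_
      out[[cv$name]] <- lab
    }
  }
  out$time <- cohort$time
  out$event <- cohort$event
  out
}

subset_cohort <- function(cohort, idx) {
  structure(
    list(X = cohort$X[idx, , drop = FALSE], R = cohort$R[idx, , drop = FALSE],
         time = cohort$time[idx], event = cohort$event[idx],
         ids = cohort$ids[idx], stats = cohort$stats, schema = cohort$schema),
    class = "encoded_cohort"
  )
}

#' Split a cohort into train / validation / test partitions
#'
#' Random, disjoint, exhaustive row partition. Partition sizes follow
#' largest-remainder rounding of `n * fractions`; remainder ties are broken
#' in favor of the later partition (so 1137 rows at fractions 0.6/0.2/0.2
#' give 682/227/228).
#'
#' @param cohort an `encoded_cohort`.
#' @param fractions three nonnegative numbers summing to 1.
#' @param seed integer; the split is deterministic given the seed.
#' @return named list of `encoded_cohort`s: `train`, `validation`, `test`.
#' @export
split_cohort <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(cohort, "encoded_cohort"), length(fractions) == 3)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop_survnet("fractions must be nonnegative and sum to 1")
  }
  n <- length(cohort$time)
  if (n < 3) stop_survnet("need at least 3 rows to split")
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- raw - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    # Largest remainder first; ties go to the later partition.
    give <- order(rem, seq_along(rem), decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1
  }
  if (any(sizes == 0)) stop_survnet("split produces an empty partition")
  perm <- with_seed(seed, sample.int(n))
  idx <- split(perm, rep(1:3, times = sizes))
  out <- lapply(idx, function(i) subset_cohort(cohort, sort(i)))
  names(out) <- c("train", "validation", "test")
  out
}
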