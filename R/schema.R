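#' Define a cohort schema
#'
#' A schema fixes the order, kind and categorical coding of the covariates in
#' a cohort. Continuous covariates are standardized at encoding time;
#' categorical covariates are mapped through an explicit label-to-code map.
#' Codes must be nonzero because zero is reserved for missing entries
#' (missing values are zero-filled and flagged in the indicator matrix).
#'
#' @param covariates a list; each element is a list with elements `name`
#'   (string), `kind` (`"continuous"` or `"categorical"`) and, for
#'   categorical covariates, `codes`: a named numeric vector mapping category
#'   labels to distinct nonzero codes.
#' @return an object of class `cohort_schema`.
#' @examples
#' sch <- cohort_schema(list(
#'   list(name = "age", kind = "continuous"),
#'   list(name = "sex", kind = "categorical", codes = c(Female = -1, Male = 1))
#' ))
#' @export
cohort_schema <- function(covariates) {
  stopifnot(is.list(covariates), length(covariates) >= 1)
  covs <- lapply(covariates, function(cv) {
    if (is.null(cv$name) || !nzchar(cv$name)) stop_survnet("every covariate needs a name")
    kind <- match.arg(cv$kind, c("continuous", "categorical"))
    codes <- NULL
    if (kind == "categorical") {
      codes <- cv$codes
      if (is.null(codes) || is.null(names(codes))) {
        stop_survnet("categorical covariate '", cv$name, "' needs a named code map")
      }
      codes <- unlist(codes)
      storage.mode(codes) <- "double"
      if (any(codes == 0)) {
        stop_survnet("covariate '", cv$name, "': code 0 is reserved for missing values")
      }
      if (anyDuplicated(codes)) {
        stop_survnet("covariate '", cv$name, "': category codes must be distinct")
      }
    }
    list(name = cv$name, kind = kind, codes = codes)
  })
  names(covs) <- vapply(covs, `[[`, character(1), "name")
  if (anyDuplicated(names(covs))) stop_survnet("covariate names must be unique")
  structure(list(covariates = covs), class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("cohort_schema with", length(x$covariates), "covariates\n")
  for (cv in x$covariates) {
    if (cv$kind == "continuous") {
      cat("  ", cv$name, ": continuous\n", sep = "")
    } else {
      cat("  ", cv$name, ": categorical {",
          paste(names(cv$codes), cv$codes, sep = "=", collapse = ", "), "}\n", sep = "")
    }
  }
  invisible(x)
}

schema_names <- function(schema) names(schema$covariates)
schema_p <- function(schema) length(schema$covariates)

# Symmetric-around-zero integer codes skipping 0: 2 levels -> -1, 1;
# 4 levels -> -2, -1, 1, 2; 5 levels -> -2, -1, 1, 2, 3.
symmetric_codes <- function(labels) {
  k <- length(labels)
  half <- floor(k / 2)
  codes <- c(seq(-half, -1), seq(1, k - half))
  stats::setNames(as.numeric(codes), labels)
}

#' Default nine-covariate NSCLC-style schema
#'
#' The covariate layout used throughout the examples and the simulator:
#' two continuous covariates (age in years, tumor size in cm) and seven
#' categorical ones (sex, five-level tumor location, differentiation grade,
#' cancer type, lymph-node management, pleura invasion, operation type).
#' Binary covariates are coded -1/+1; multi-level covariates use integer
#' codes symmetric around zero, skipping 0 (reserved for missing).
#'
#' @return a [cohort_schema()].
#' @export
nsclc_schema <- function() {
  cohort_schema(list(
    list(name = "age", kind = "continuous"),
    list(name = "tumor_size", kind = "continuous"),
    list(name = "sex", kind = "categorical",
         codes = c(Female = -1, Male = 1)),
    list(name = "tumor_location", kind = "categorical",
         codes = symmetric_codes(c("LeftUpper", "LeftLower", "RightUpper",
                                   "RightMiddle", "RightLower"))),
    list(name = "differentiation", kind = "categorical",
         codes = c(Lower = -1, MiddleOrHigh = 1)),
    list(name = "cancer_type", kind = "categorical",
         codes = c(Adenocarcinoma = -1, Squamous = 1)),
    list(name = "lymph_node", kind = "categorical",
         codes = c(Dissection = -1, BiopsyOrNone = 1)),
    list(name = "pleura_invasion", kind = "categorical",
         codes = c(No = -1, Yes = 1)),
    list(name = "operation", kind = "categorical",
         codes = c(Lobectomy = -1, SubLobectomy = 1))
  ))
}

#' Read / write a schema file
#'
#' Schemas are stored as JSON: a list of covariate descriptors with `name`,
#' `kind`, and (for categorical kinds) a `codes` map.
#'
#' @param path file path.
#' @return `read_schema` returns a [cohort_schema()].
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  covs <- lapply(obj$covariates, function(cv) {
    if (!is.null(cv$codes)) cv$codes <- unlist(cv$codes)
    cv
  })
  cohort_schema(covs)
}

#' @rdname read_schema
#' @param schema a [cohort_schema()].
#' @export
write_schema <- function(schema, path) {
  obj <- list(covariates = lapply(schema$covariates, function(cv) {
    out <- list(name = cv$name, kind = cv$kind)
    if (!is.null(cv$codes)) out$codes <- as.list(cv$codes)
    out
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
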