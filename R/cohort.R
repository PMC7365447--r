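#' Required cohort columns
#'
#' A cohort table holds one row per person: gender (\code{"M"}/\code{"F"}),
#' age in years, weight in kg, height in cm and the eight segmental
#' impedances \code{R1}--\code{R8} in ohms (left upper limb, upper trunk,
#' right upper limb, left trunk, right trunk, lower trunk, left lower limb,
#' right lower limb). An optional \code{PBF} column carries the observed
#' percentage body fat.
#'
#' @keywords internal
#' @name cohort-format
NULL

.impedance_cols <- paste0("R", 1:8)
.cohort_cols <- c("gender", "age", "weight", "height", .impedance_cols)

#' Validate a data frame as a BIA cohort
#'
#' Checks the column schema and the physiological invariants (positive
#' height, weight and impedances; PBF within 0--100 when present) and
#' returns the table classed as a cohort.
#'
#' @param x data frame with columns `gender`, `age`, `weight`, `height`,
#'   `R1`..`R8` and optionally `PBF`.
#' @param identifier short label carried along for reporting.
#' @return the validated data frame, classed `"pbf_cohort"`.
#' @export
as_pbf_cohort <- function(x, identifier = "cohort") {
  if (!is.data.frame(x)) stop("cohort must be a data frame", call. = FALSE)
  if (nrow(x) == 0L) stop("cohort is empty", call. = FALSE)
  missing_cols <- setdiff(.cohort_cols, names(x))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$gender <- as.character(x$gender)
  bad_g <- which(!x$gender %in% c("M", "F"))
  if (length(bad_g)) {
    stop("invalid gender value in row(s) ", paste(bad_g, collapse = ", "),
         " (expected \"M\" or \"F\")", call. = FALSE)
  }
  num_cols <- c("age", "weight", "height", .impedance_cols,
                intersect("PBF", names(x)))
  for (cl in num_cols) {
    v <- x[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric value in column ", cl, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing value in column ", cl, " at row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
  }
  if (any(x$age < 0)) stop("age must be non-negative", call. = FALSE)
  if (any(x$weight <= 0)) stop("weight must be strictly positive", call. = FALSE)
  if (any(x$height <= 0)) stop("height must be strictly positive", call. = FALSE)
  for (cl in .impedance_cols) {
    bad <- which(x[[cl]] <= 0)
    if (length(bad)) {
      stop("impedance ", cl, " must be strictly positive (row(s) ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  if ("PBF" %in% names(x) && any(x$PBF < 0 | x$PBF > 100)) {
    stop("PBF must lie in [0, 100]", call. = FALSE)
  }
  structure(x,
            identifier = identifier,
            class = unique(c("pbf_cohort", class(x))))
}

#' Read a cohort table
#'
#' Reads a cohort from CSV (comma-separated, header row, '.' decimal) or
#' XLSX (first sheet; requires the readxl package) and validates it with
#' [as_pbf_cohort()]. Row order is preserved. The `PBF` column is optional
#' so prediction-only cohorts can be read.
#'
#' @param path file to read.
#' @param format `"csv"` (default) or `"xlsx"`.
#' @param identifier label for the cohort; defaults to the file name.
#' @return a `"pbf_cohort"` data frame.
#' @export
read_cohort <- function(path, format = c("csv", "xlsx"),
                        identifier = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the readxl package", call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path))
    })
  as_pbf_cohort(x, identifier = identifier)
}

#' Write a cohort table to CSV
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param cohort a cohort data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, intersect(c(.cohort_cols, "PBF"), names(cohort))]
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numeric coding of gender
#'
#' Fixed convention: `"M"` is 1, `"F"` is 0. Documented so that the sign of
#' the gender coefficient in the fitted model is interpretable.
#'
#' @param g character vector of `"M"`/`"F"`.
#' @return numeric vector of 0/1.
#' @export
encode_gender <- function(g) {
  g <- as.character(g)
  bad <- which(!g %in% c("M", "F"))
  if (length(bad)) {
    stop("invalid gender value(s): ", paste(unique(g[bad]), collapse = ", "),
         call. = FALSE)
  }
  as.numeric(g == "M")
}

#' The reference feature set of the PBF model
#'
#' The nine features of the linear PBF model, in model order: gender code G,
#' age A, weight W, height H, the impedance products R1R2, R2R3 and R4R5,
#' the upper-trunk impedance R2, and the impedance index H2/R2
#' (height squared over R2, the classic BIA resistance index).
#'
#' @return character vector of nine feature names.
#' @export
pbf_reference_features <- function() {
  c("G", "A", "W", "H", "R1R2", "R2R3", "R4R5", "R2", "H2/R2")
}

#' Build the candidate feature table
#'
#' Expands a cohort into the 64-column candidate feature set: the twelve
#' first-order features G (gender code), A, W, H and R1..R8, followed by the
#' second-order features Ri2 (squares, 8), 1/Ri (reciprocals, 8), RiRj for
#' i < j (pairwise products, 28) and H2/Ri (height-squared over impedance,
#' 8). Naming is deterministic: squares are `"R12"`..`"R82"`, reciprocals
#' `"1/R1"`.., products `"R1R2"`.. and indices `"H2/R1"`.. Any additional
#' numeric covariates can be carried through `extra`.
#'
#' @param cohort a cohort data frame.
#' @param extra optional data frame (or named matrix) of additional numeric
#'   columns, one row per sample, appended unchanged.
#' @return an object of class `"candidate_features"`: a list with `values`
#'   (numeric matrix), `feature_names`, `target` (PBF vector or NULL) and
#'   `distance_features` (the first-order columns used as the neighbour
#'   metric basis).
#' @export
build_candidate_features <- function(cohort, extra = NULL) {
  cohort <- as_pbf_cohort(as.data.frame(cohort),
                          identifier = attr(cohort, "identifier") %||% "cohort")
  n <- nrow(cohort)
  R <- as.matrix(cohort[, .impedance_cols])
  for (j in 1:8) {
    bad <- which(R[, j] == 0)
    if (length(bad)) {
      stop("cannot form reciprocal features: impedance R", j,
           " is zero for sample(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  first <- cbind(G = encode_gender(cohort$gender),
                 A = as.numeric(cohort$age),
                 W = cohort$weight,
                 H = cohort$height,
                 R)
  squares <- R^2
  colnames(squares) <- paste0(.impedance_cols, "2")
  recips <- 1 / R
  colnames(recips) <- paste0("1/", .impedance_cols)
  prods <- matrix(0, n, 28)
  pn <- character(28)
  k <- 0L
  for (i in 1:7) for (j in (i + 1):8) {
    k <- k + 1L
    prods[, k] <- R[, i] * R[, j]
    pn[k] <- paste0("R", i, "R", j)
  }
  colnames(prods) <- pn
  h2r <- cohort$height^2 / R
  colnames(h2r) <- paste0("H2/", .impedance_cols)
  values <- cbind(first, squares, recips, prods, h2r)
  if (!is.null(extra)) {
    extra <- as.matrix(as.data.frame(extra))
    if (nrow(extra) != n) stop("extra columns must have one row per sample",
                               call. = FALSE)
    storage.mode(extra) <- "double"
    values <- cbind(values, extra)
  }
  rownames(values) <- NULL
  structure(list(values = values,
                 feature_names = colnames(values),
                 target = if ("PBF" %in% names(cohort)) cohort$PBF else NULL,
                 distance_features = colnames(first)),
            class = "candidate_features")
}

#' @export
print.candidate_features <- function(x, ...) {
  cat("Candidate feature table:", nrow(x$values), "samples x",
      ncol(x$values), "features\n")
  cat("Target (PBF):", if (is.null(x$target)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
as.data.frame.candidate_features <- function(x, ...) {
  out <- as.data.frame(x$values, check.names = FALSE)
  if (!is.null(x$target)) out$PBF <- x$target
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
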