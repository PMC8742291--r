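#' Clinical feature codebook
#'
#' The fixed set of clinical features recognized in a screening-cohort table:
#' SSN enrolment status, account number, gender, age, race, and the laboratory
#' panel (TSH, PSA, HBsAb, HBsAg, GLU, CHOL, TG, HDL, LDL, CHOL/HDL). The
#' codebook records, for each feature, its kind (\code{binary},
#' \code{categorical}, \code{identifier} or \code{continuous}), its units, and
#' the admissible levels for coded fields. The numeric coding used downstream
#' (see \code{\link{encode_features}}) is a declared convention of this
#' package, not a clinical standard.
#'
#' @return A named list of feature descriptors, class \code{risk_codebook}.
#' @examples
#' cb <- default_codebook()
#' names(cb)
#' @export
default_codebook <- function() {
  cb <- list(
    ssn_status     = list(kind = "binary", units = "", levels = c("SSN-", "SSN+")),
    account_number = list(kind = "identifier", units = "", levels = NULL),
    gender         = list(kind = "binary", units = "", levels = c("M", "F")),
    age            = list(kind = "continuous", units = "years", levels = NULL),
    race           = list(kind = "categorical", units = "",
                          levels = c("chinese", "other_asian", "other")),
    tsh            = list(kind = "continuous", units = "mIU/L", levels = NULL),
    psa            = list(kind = "continuous", units = "ng/mL", levels = NULL),
    hbsab          = list(kind = "binary", units = "", levels = c("neg", "pos")),
    hbsag          = list(kind = "binary", units = "", levels = c("neg", "pos")),
    glu            = list(kind = "continuous", units = "mg/dL", levels = NULL),
    chol           = list(kind = "continuous", units = "mg/dL", levels = NULL),
    tg             = list(kind = "continuous", units = "mg/dL", levels = NULL),
    hdl            = list(kind = "continuous", units = "mg/dL", levels = NULL),
    ldl            = list(kind = "continuous", units = "mg/dL", levels = NULL),
    chol_hdl       = list(kind = "continuous", units = "ratio", levels = NULL)
  )
  structure(cb, class = "risk_codebook")
}

# Lab columns that must be non-negative when present.
.lab_features <- c("tsh", "psa", "glu", "chol", "tg", "hdl", "ldl", "chol_hdl")

#' Construct a cohort table
#'
#' Wraps a patient-level data frame (one row per record, columns named by the
#' codebook, \code{NA} for missing) into a validated \code{cohort_table}.
#' Continuous lab values must be non-negative when present. When \code{chol},
#' \code{hdl} and \code{chol_hdl} are all present, the stored ratio is checked
#' against \code{chol/hdl} at 5\% relative tolerance; discordant rows are
#' flagged (attribute \code{ratio_flags}) with a warning but never
#' auto-corrected.
#'
#' @param data data frame with exactly the codebook's feature columns.
#' @param codebook a \code{risk_codebook}; defaults to
#'   \code{\link{default_codebook}}.
#' @return An object of class \code{cohort_table}: a list with elements
#'   \code{data} and \code{codebook}.
#' @export
cohort_table <- function(data, codebook = default_codebook()) {
  stopifnot(is.data.frame(data))
  feats <- names(codebook)
  unknown <- setdiff(names(data), feats)
  if (length(unknown) > 0L) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(feats, names(data))
  if (length(absent) > 0L) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  data <- data[feats]
  for (f in feats) {
    kind <- codebook[[f]]$kind
    if (kind %in% c("binary", "categorical")) {
      v <- as.character(data[[f]])
      bad <- which(!is.na(v) & !(v %in% codebook[[f]]$levels))
      if (length(bad) > 0L) {
        stop(sprintf("invalid level '%s' for '%s' at row %d",
                     v[bad[1L]], f, bad[1L]), call. = FALSE)
      }
      data[[f]] <- v
    } else if (kind == "continuous") {
      data[[f]] <- as.numeric(data[[f]])
    }
  }
  for (f in .lab_features) {
    bad <- which(!is.na(data[[f]]) & data[[f]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("negative value for '%s' at row %d", f, bad[1L]),
           call. = FALSE)
    }
  }
  flags <- integer(0)
  full <- which(!is.na(data$chol) & !is.na(data$hdl) & !is.na(data$chol_hdl) &
                  data$hdl > 0)
  if (length(full) > 0L) {
    implied <- data$chol[full] / data$hdl[full]
    rel <- abs(implied - data$chol_hdl[full]) / pmax(abs(data$chol_hdl[full]),
                                                     .Machine$double.eps)
    flags <- full[rel > 0.05]
    if (length(flags) > 0L) {
      warning(length(flags), " record(s) with CHOL/HDL ratio discordant ",
              "with CHOL and HDL (>5% relative); rows flagged, not corrected",
              call. = FALSE)
    }
  }
  structure(list(data = data, codebook = codebook),
            class = "cohort_table", ratio_flags = flags)
}

#' @export
print.cohort_table <- function(x, ...) {
  n_missing <- sum(is.na(x$data))
  cat(sprintf("cohort_table: %d records x %d features (%d missing values)\n",
              nrow(x$data), ncol(x$data), n_missing))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

#' @export
as.data.frame.cohort_table <- function(x, ...) x$data

#' Read a cohort CSV file
#'
#' Comma-separated, UTF-8, header row required, \code{"."} decimal separator.
#' Empty cells become missing values; row order is preserved. Columns not in
#' the codebook, or codebook columns absent from the file, are an error.
#'
#' @param path path to a CSV file.
#' @param codebook a \code{risk_codebook}.
#' @return A \code{\link{cohort_table}}.
#' @export
read_cohort_csv <- function(path, codebook = default_codebook()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE,
                         fileEncoding = "UTF-8")
  for (f in names(codebook)) {
    if (codebook[[f]]$kind == "continuous" && f %in% names(raw)) {
      v <- raw[[f]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("malformed value '%s' in column '%s' at row %d",
                     v[bad[1L]], f, bad[1L]), call. = FALSE)
      }
      raw[[f]] <- num
    }
  }
  cohort_table(raw, codebook)
}

#' Write a cohort table to CSV
#'
#' Inverse of \code{\link{read_cohort_csv}}: missing values are written as
#' empty cells; an empty cohort yields a header-only file.
#'
#' @param cohort a \code{cohort_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Encode a cohort into the non-negative target matrix
#'
#' Builds the non-negative target matrix \eqn{X} (patients by features) and the
#' binary observation mask \eqn{M} (1 = observed) consumed by
#' \code{\link{fit_ognmf}}. The encoding is strictly positive on observed
#' cells so that multiplicative updates cannot permanently zero a factor
#' entry:
#' \itemize{
#'   \item SSN status expands to the two complementary indicator columns
#'     \code{ssn_pos}/\code{ssn_neg}, coded \{1, 2\}, mirroring the convention
#'     that enrolment with and without an SSN are counted as separate
#'     features; other binary fields code their two levels as \{1, 2\}.
#'   \item Categorical race codes its levels as consecutive positive integers
#'     in codebook order.
#'   \item Continuous columns (and, when included, the account number) are
#'     min-max scaled to \[0, 1\] over their observed entries; the per-column
#'     affine map is stored so the encoding is invertible
#'     (\code{\link{decode_column}}).
#' }
#' Unobserved cells hold the column's observed mean in scaled space as a
#' placeholder; the masked objective never reads them, but update rules that
#' touch \eqn{X} always see a finite value. With the account number included
#' (the default) the matrix has 16 columns.
#'
#' @param cohort a \code{cohort_table}.
#' @param include_account include the account number as a min-max scaled
#'   positive column? It is an identifier with no plausible clinical signal,
#'   but it is part of the full 16-feature set; set \code{FALSE} to drop it.
#' @return An object of class \code{feature_matrix}: list with \code{X},
#'   \code{M}, \code{scaling} (per-column inverse-map metadata) and
#'   \code{features}.
#' @export
encode_features <- function(cohort, include_account = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  cb <- cohort$codebook
  n <- nrow(d)
  if (n == 0L) stop("cohort is empty", call. = FALSE)

  cols <- list()
  scaling <- list()

  add_col <- function(name, x, m, sc) {
    cols[[name]] <<- x
    attr(cols[[name]], "mask") <<- m
    scaling[[name]] <<- sc
  }

  # SSN status -> two complementary strictly-positive indicators
  ssn <- d$ssn_status
  m_ssn <- as.numeric(!is.na(ssn))
  pos <- ifelse(is.na(ssn), NA_real_, ifelse(ssn == "SSN+", 2, 1))
  neg <- ifelse(is.na(ssn), NA_real_, ifelse(ssn == "SSN-", 2, 1))
  add_col("ssn_pos", pos, m_ssn, list(kind = "indicator", source = "ssn_status",
                                      level = "SSN+"))
  add_col("ssn_neg", neg, m_ssn, list(kind = "indicator", source = "ssn_status",
                                      level = "SSN-"))

  for (f in setdiff(names(cb), "ssn_status")) {
    kind <- cb[[f]]$kind
    if (f == "account_number" && !include_account) next
    if (kind == "binary") {
      v <- d[[f]]
      m <- as.numeric(!is.na(v))
      x <- as.numeric(match(v, cb[[f]]$levels))  # {1, 2}
      add_col(f, x, m, list(kind = "binary", levels = cb[[f]]$levels))
    } else if (kind == "categorical") {
      v <- d[[f]]
      m <- as.numeric(!is.na(v))
      x <- as.numeric(match(v, cb[[f]]$levels))  # 1..L
      add_col(f, x, m, list(kind = "categorical", levels = cb[[f]]$levels))
    } else {  # continuous or identifier: min-max scale observed entries
      v <- if (kind == "identifier") {
        suppressWarnings(as.numeric(d[[f]]))
      } else d[[f]]
      if (kind == "identifier" && any(!is.na(d[[f]]) & is.na(v))) {
        # non-numeric identifiers: rank by first appearance
        ids <- unique(d[[f]][!is.na(d[[f]])])
        v <- as.numeric(match(d[[f]], ids))
      }
      m <- as.numeric(!is.na(v))
      if (all(m == 0)) {
        stop(sprintf("column '%s' is entirely missing; scaling undefined", f),
             call. = FALSE)
      }
      lo <- min(v, na.rm = TRUE)
      hi <- max(v, na.rm = TRUE)
      rng <- if (hi > lo) hi - lo else 1
      x <- (v - lo) / rng
      add_col(f, x, m, list(kind = "continuous", offset = lo, scale = rng))
    }
  }

  X <- do.call(cbind, lapply(cols, as.numeric))
  M <- do.call(cbind, lapply(cols, function(c) attr(c, "mask")))
  colnames(X) <- colnames(M) <- names(cols)
  # placeholder: column mean of observed entries, in scaled space
  for (j in seq_len(ncol(X))) {
    obs <- M[, j] == 1
    if (!any(obs)) {
      stop(sprintf("column '%s' is entirely missing; scaling undefined",
                   colnames(X)[j]), call. = FALSE)
    }
    X[!obs, j] <- mean(X[obs, j])
  }
  stopifnot(all(is.finite(X)), all(X >= 0))
  structure(list(X = X, M = M, scaling = scaling, features = colnames(X)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d x %d, %.1f%% observed\n",
              nrow(x$X), ncol(x$X), 100 * mean(x$M)))
  invisible(x)
}

#' Decode a continuous column back to clinical units
#'
#' Applies the stored inverse affine map of a continuous (or identifier)
#' column to values in scaled space — typically cells of a reconstruction
#' \eqn{\hat X = UV} — and clips the result at the clinical floor of zero
#' (solver undershoot below the scaled-space origin cannot produce a negative
#' lab value).
#'
#' @param fm a \code{feature_matrix}.
#' @param Xhat numeric matrix with the same shape as \code{fm$X}, or a numeric
#'   vector of scaled values for the column.
#' @param column feature name of a continuous column.
#' @return Numeric vector in clinical units.
#' @export
decode_column <- function(fm, Xhat, column) {
  stopifnot(inherits(fm, "feature_matrix"))
  sc <- fm$scaling[[column]]
  if (is.null(sc)) stop("unknown column: ", column, call. = FALSE)
  if (sc$kind != "continuous") {
    stop("column '", column, "' is not continuous", call. = FALSE)
  }
  x <- if (is.matrix(Xhat)) {
    if (!all(dim(Xhat) == dim(fm$X))) {
      stop("Xhat shape does not match the feature matrix", call. = FALSE)
    }
    Xhat[, column]
  } else as.numeric(Xhat)
  pmax(sc$offset + x * sc$scale, 0)
}
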