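# Delimited-text interchange: plain CSV, UTF-8, "." decimal. Times are years
# as reals; converting visit dates to years from blood draw is the caller's
# concern (e.g. as.numeric(visit_date - draw_date) / 365.25).

#' Read a protein abundance matrix from CSV
#'
#' Expects the first column to be `sample_id` and the remaining columns
#' numeric protein abundances; blank cells become missing values.
#'
#' @param path CSV file path.
#' @return Numeric matrix, samples x proteins, with ids as dimnames.
#' @export
read_protein_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop("protein CSV must start with a sample_id column")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      v[v == ""] <- NA
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop(sprintf("malformed numeric cell at row %d, column '%s'",
                     bad[1], names(vals)[j]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a protein abundance matrix to CSV
#' @param matrix Samples x proteins matrix with dimnames.
#' @param path Output path.
#' @export
write_protein_csv <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read sample metadata (group and outcome labels) from CSV
#' @param path CSV with columns `sample_id`, `group`, `outcome`.
#' @return Validated `data.frame`.
#' @export
read_meta_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "outcome")
  if (!all(need %in% names(df)))
    stop("meta CSV needs columns sample_id, group, outcome")
  if (!all(df$group %in% c("case", "control")))
    stop("group must be case/control")
  ok <- c("progressor", "non_progressor", "not_applicable")
  if (!all(df$outcome %in% ok))
    stop("outcome must be one of ", paste(ok, collapse = "/"))
  bad <- xor(df$outcome == "not_applicable", df$group == "control")
  if (any(bad))
    stop("outcome must be not_applicable exactly for controls; offending: ",
         paste(df$sample_id[bad], collapse = ", "))
  df
}

#' Write sample metadata to CSV
#' @param meta Metadata `data.frame`.
#' @param path Output path.
#' @export
write_meta_csv <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read interval-censored observations from CSV
#'
#' Columns `sample_id`, `L_years`, `R_years`; `R_years` accepts `inf`,
#' `Inf` or an empty cell for right censoring.
#'
#' @param path CSV file path.
#' @return `data.frame` with `sample_id`, `L`, `R` (validated, `R = Inf`
#'   for right-censored).
#' @export
read_intervals_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(R_years = "character"))
  need <- c("sample_id", "L_years", "R_years")
  if (!all(need %in% names(df)))
    stop("intervals CSV needs columns sample_id, L_years, R_years")
  r <- trimws(df$R_years)
  r[r %in% c("", "inf", "Inf", "INF")] <- "Inf"
  suppressWarnings(R <- as.numeric(r))
  bad <- which(is.na(R))
  if (length(bad))
    stop("malformed R_years at row ", bad[1])
  out <- data.frame(sample_id = as.character(df$sample_id),
                    L = as.numeric(df$L_years), R = R,
                    stringsAsFactors = FALSE)
  .check_intervals(out)
  out
}

#' Write interval-censored observations to CSV
#' @param obs `data.frame` with `sample_id`, `L`, `R`.
#' @param path Output path; right censoring is written as `inf`.
#' @export
write_intervals_csv <- function(obs, path) {
  .check_intervals(obs)
  df <- data.frame(sample_id = obs$sample_id, L_years = obs$L,
                   R_years = ifelse(is.finite(obs$R),
                                    as.character(obs$R), "inf"),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
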