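# File formats: summary-statistics tables, panel matrices / VCF hard calls,
# and the results table.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a summary-statistics table
#'
#' Tab- or comma-delimited file with a header; required columns
#' `variant_id`, `beta_marginal` and `n` (the original-study sample size,
#' constant across rows). Optional columns `chrom` and `pos` are carried
#' through untouched.
#'
#' @param path File path.
#' @return A `marginal_stats` object (with the source table attached as
#'   attribute `table`).
#' @export
read_summary_stats <- function(path) {
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = NA, stringsAsFactors = FALSE,
                           na.strings = character())
  need <- c("variant_id", "beta_marginal", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("summary-statistics file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dup <- tab$variant_id[duplicated(tab$variant_id)]
  if (length(dup))
    stop("duplicate variant_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  beta <- suppressWarnings(as.numeric(tab$beta_marginal))
  bad <- which(!is.finite(beta))
  if (length(bad))
    stop("non-numeric beta_marginal at data line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- suppressWarnings(as.integer(tab$n))
  if (anyNA(n) || length(unique(n)) != 1L)
    stop("column `n` must hold a single integer sample size for the whole file",
         call. = FALSE)
  out <- marginal_stats(beta, n_o = n[1], variant_ids = as.character(tab$variant_id))
  attr(out, "table") <- tab
  out
}

#' Read a reference panel
#'
#' Either a delimited numeric matrix (rows = individuals, header =
#' variant ids) or a VCF restricted to biallelic sites with hard `GT`
#' calls. Genotypes are coded as minor-allele dosages 0/1/2, with "minor"
#' defined within the panel; columns are subset and reordered to
#' `variant_ids` and then standardized.
#'
#' @param path File path.
#' @param format `"matrix"` or `"vcf"`.
#' @param variant_ids Character vector of variant ids to extract, in the
#'   order of the matching summary statistics; `NULL` keeps all columns in
#'   file order.
#' @param missing `"error"` (default) or `"impute"` (mean imputation of
#'   missing genotypes before standardization).
#' @return A `standardized_panel`.
#' @export
read_panel <- function(path, format = c("matrix", "vcf"), variant_ids = NULL,
                       missing = c("error", "impute")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  raw <- if (format == "matrix") .read_panel_matrix(path) else .read_panel_vcf(path)
  if (!is.null(variant_ids)) {
    absent <- setdiff(variant_ids, colnames(raw))
    if (length(absent))
      stop("variant(s) absent from the panel: ", paste(absent, collapse = ", "),
           call. = FALSE)
    raw <- raw[, variant_ids, drop = FALSE]
  }
  if (anyNA(raw)) {
    if (missing == "error")
      stop("panel contains missing genotypes; use missing = \"impute\" to mean-impute",
           call. = FALSE)
    for (j in which(colSums(is.na(raw)) > 0)) {
      mu <- mean(raw[, j], na.rm = TRUE)
      raw[is.na(raw[, j]), j] <- mu
    }
  }
  standardize_panel(raw)
}

.read_panel_matrix <- function(path) {
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("panel matrix has non-numeric entries", call. = FALSE)
  m
}

.read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning("skipping ", sum(multi), " multiallelic site(s)")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  # dosage of the ALT allele from hard calls
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(al)
             sum(al == "1"), numeric(1)))
  }
  dos <- apply(gt, 1L, count_alt)            # samples x sites
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  colnames(dos) <- ids
  # orient to the minor allele within the panel
  for (j in seq_len(ncol(dos))) {
    f <- mean(dos[, j], na.rm = TRUE) / 2
    if (is.finite(f) && f > 0.5) dos[, j] <- 2 - dos[, j]
  }
  dos
}

#' Write a results table
#'
#' Tab-delimited table with one row per variant (see
#' [as.data.frame.region_result()]); numeric fields are written at full
#' precision so a write/read round trip is exact.
#'
#' @param result A `region_result`.
#' @param path Output path.
#' @return Invisibly, the written data frame.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "region_result"))
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
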