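#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm pchisq pt qnorm median setNames rnorm runif sd
#' @importFrom utils read.delim write.table combn
NULL

# canonical column order for summary-statistics tables
SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

#' Construct a validated GWAS summary-statistics table
#'
#' Builds a `sumstats` object (a tibble with trait metadata) from a data
#' frame holding one row per SNP. Rows violating the per-record invariants
#' (identical alleles, non-positive standard error, allele frequency outside
#' \[0, 1\], position below 1, p-value outside (0, 1\], non-positive sample
#' size, non-finite effect) are rejected and collected in a rejection report
#' attached as the `"rejected"` attribute. Alleles are uppercased; p-values
#' of exactly zero are replaced by the smallest positive double and flagged
#' (attribute `"flagged"`) so that downstream log transforms stay finite.
#'
#' @param df data frame with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name label for the trait.
#' @param trait_type `"binary"` (effects on the log-odds scale) or
#'   `"continuous"`.
#' @return A `sumstats` tibble in canonical column order, preserving input
#'   row order for accepted rows. Attributes: `trait_name`, `trait_type`,
#'   `rejected` (tibble of `rsid`, `reason`), `flagged` (tibble of `rsid`,
#'   `flag`).
#' @export
sumstats <- function(df, trait_name, trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as_tibble(df)[SUMSTATS_COLS]
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  flagged <- tibble(rsid = character(), flag = character())
  zero_p <- !is.na(df$pval) & df$pval == 0
  if (any(zero_p)) {
    df$pval[zero_p] <- .Machine$double.xmin
    flagged <- rbind(flagged,
                     tibble(rsid = df$rsid[zero_p], flag = "pval_zero_replaced"))
  }

  reason <- rep(NA_character_, nrow(df))
  set_reason <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  set_reason(is.na(df$rsid) | df$rsid == "", "missing_rsid")
  set_reason(is.na(df$beta) | !is.finite(df$beta), "non_finite_beta")
  set_reason(is.na(df$se) | df$se <= 0, "non_positive_se")
  set_reason(is.na(df$eaf) | df$eaf < 0 | df$eaf > 1, "eaf_out_of_range")
  set_reason(is.na(df$pos) | df$pos < 1, "invalid_position")
  set_reason(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval_out_of_range")
  set_reason(is.na(df$n) | df$n <= 0 | df$n != round(df$n), "invalid_n")
  set_reason(df$effect_allele == df$other_allele, "identical_alleles")

  rejected <- tibble(rsid = df$rsid[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  kept <- df[is.na(reason), , drop = FALSE]

  dup <- kept$rsid[duplicated(kept$rsid)]
  if (length(dup) > 0) {
    stop("duplicate rsid in summary statistics: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  structure(kept,
            class = c("sumstats", class(kept)),
            trait_name = trait_name,
            trait_type = trait_type,
            rejected = rejected,
            flagged = flagged)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0) cat(sprintf(", %d rejected rows", nrow(rej)))
  cat("\n")
  NextMethod()
}

#' Rejected rows of a summary-statistics table
#'
#' @param stats a `sumstats` object.
#' @return Tibble with columns `rsid` and `reason`, one row per input row
#'   that failed validation on construction or read.
#' @export
rejected_rows <- function(stats) {
  rej <- attr(stats, "rejected")
  if (is.null(rej)) tibble(rsid = character(), reason = character()) else rej
}

#' Trait metadata accessors
#'
#' @param stats a `sumstats` object.
#' @return The trait name or type stored on the object.
#' @export
trait_name <- function(stats) attr(stats, "trait_name")

#' @rdname trait_name
#' @export
trait_type <- function(stats) attr(stats, "trait_type")

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table (delimiter auto-detected from the
#' header line, tab preferred) with one row per SNP, optionally remapping
#' column names, and validates it via [sumstats()]. Rows failing the record
#' invariants are rejected, not fatal; the per-row report is available via
#' [rejected_rows()] and can be written with [write_rejection_report()].
#'
#' @param path file path.
#' @param trait_name trait label; defaults to the file name.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(rsid = "SNP", pval = "P")`.
#' @return A `sumstats` object preserving file row order.
#' @export
read_sumstats <- function(path, trait_name = basename(path),
                          trait_type = c("binary", "continuous"),
                          column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("column_map names absent column '", src, "' for '", canon, "'",
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  sumstats(df, trait_name = trait_name, trait_type = trait_type)
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Writes the canonical ten-column header; floating-point fields are
#' rendered with full double precision (17 significant digits) so that
#' `read_sumstats(write_sumstats(x))` reproduces `x` exactly.
#'
#' @param stats a `sumstats` object.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(stats, path) {
  out <- as.data.frame(stats)[SUMSTATS_COLS]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write summary statistics to '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Write the per-row rejection report of a summary-statistics read
#'
#' @param stats a `sumstats` object.
#' @param path output TSV path (columns `rsid`, `reason`).
#' @return Invisibly, `path`.
#' @export
write_rejection_report <- function(stats, path) {
  write.table(as.data.frame(rejected_rows(stats)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
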