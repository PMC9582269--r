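COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_simple_allele <- function(x) x %in% names(COMPLEMENT)

is_palindromic <- function(ea, oa) {
  is_simple_allele(ea) & is_simple_allele(oa) & COMPLEMENT[ea] == oa
}

#' Build a validated LD-proxy map
#'
#' A proxy map substitutes, for instruments absent from an outcome study, a
#' nearby variant in strong LD. Each entry carries the allele correspondence
#' between target and proxy so effects can be translated back onto the
#' target's alleles. Entries with r-squared at or below 0.60 are rejected at
#' validation: weaker proxies are not acceptable substitutes.
#'
#' @param df data frame with columns `target_rsid`, `proxy_rsid`, `r2`,
#'   `target_ea`, `proxy_ea`, `target_oa`, `proxy_oa` (the proxy alleles
#'   corresponding to the target's effect and other alleles).
#' @return A `proxy_map` tibble.
#' @export
proxy_map <- function(df) {
  cols <- c("target_rsid", "proxy_rsid", "r2", "target_ea", "proxy_ea",
            "target_oa", "proxy_oa")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("proxy map missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as_tibble(df)[cols]
  for (col in c("target_ea", "proxy_ea", "target_oa", "proxy_oa")) {
    df[[col]] <- toupper(as.character(df[[col]]))
  }
  if (any(df$r2 <= 0.60)) {
    bad <- df$target_rsid[df$r2 <= 0.60]
    stop("proxy r2 must exceed 0.60; rejected: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("proxy_map", class(df)))
}

#' Read a proxy map from TSV
#'
#' @param path TSV with the columns documented in [proxy_map()].
#' @return A validated `proxy_map`.
#' @export
read_proxy_map <- function(path) {
  proxy_map(read.delim(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE))
}

#' Substitute proxy records for instruments missing from an outcome study
#'
#' For each missing rsid with a proxy-map entry whose proxy is present in
#' the outcome summary statistics, returns the proxy's outcome record
#' rewritten onto the target's alleles (effect sign and allele frequency
#' reflected through the stated allele correspondence). Proxy effect sizes
#' are used as-is, without attenuation by r-squared. Missing rsids with no
#' usable proxy are reported as unproxied and the analysis proceeds on the
#' reduced instrument set.
#'
#' @param outcome a `sumstats` object for the outcome trait.
#' @param missing rsids absent from the outcome.
#' @param proxies a [proxy_map()] or `NULL`.
#' @return List with `records` (tibble of substituted outcome rows keyed by
#'   the target rsid) and `report` (tibble `rsid`, `status`
#'   (`proxied`/`unproxied`), `proxy_rsid`).
#' @export
apply_proxies <- function(outcome, missing, proxies = NULL) {
  report <- tibble(rsid = character(), status = character(),
                   proxy_rsid = character())
  records <- NULL
  for (rs in missing) {
    entry <- if (is.null(proxies)) NULL else
      proxies[proxies$target_rsid == rs, , drop = FALSE]
    if (is.null(entry) || nrow(entry) == 0) {
      report <- rbind(report, tibble(rsid = rs, status = "unproxied",
                                     proxy_rsid = NA_character_))
      next
    }
    entry <- entry[1, ]
    hit <- which(outcome$rsid == entry$proxy_rsid)
    if (length(hit) == 0) {
      report <- rbind(report, tibble(rsid = rs, status = "unproxied",
                                     proxy_rsid = entry$proxy_rsid))
      next
    }
    rec <- as.data.frame(outcome)[hit, , drop = FALSE]
    # rewrite the proxy record onto the target's allele coordinates
    if (rec$effect_allele == entry$proxy_ea && rec$other_allele == entry$proxy_oa) {
      # proxy effect allele corresponds to the target effect allele
    } else if (rec$effect_allele == entry$proxy_oa &&
               rec$other_allele == entry$proxy_ea) {
      rec$beta <- -rec$beta
      rec$eaf <- 1 - rec$eaf
    } else {
      report <- rbind(report, tibble(rsid = rs, status = "unproxied",
                                     proxy_rsid = entry$proxy_rsid))
      next
    }
    rec$rsid <- rs
    rec$effect_allele <- entry$target_ea
    rec$other_allele <- entry$target_oa
    records <- rbind(records, rec)
    report <- rbind(report, tibble(rsid = rs, status = "proxied",
                                   proxy_rsid = entry$proxy_rsid))
  }
  list(records = if (is.null(records)) NULL else as_tibble(records),
       report = report)
}

align_alleles <- function(ea_exp, oa_exp, ea_out, oa_out) {
  # returns "same", "swap", or "mismatch", complementing the outcome
  # alleles when the direct comparison fails (strand flip)
  if (ea_out == ea_exp && oa_out == oa_exp) return("same")
  if (ea_out == oa_exp && oa_out == ea_exp) return("swap")
  if (is_simple_allele(ea_out) && is_simple_allele(oa_out)) {
    cea <- unname(COMPLEMENT[ea_out]); coa <- unname(COMPLEMENT[oa_out])
    if (cea == ea_exp && coa == oa_exp) return("same")
    if (cea == oa_exp && coa == ea_exp) return("swap")
  }
  "mismatch"
}

#' Harmonize exposure and outcome effects to shared effect alleles
#'
#' For each instrument, aligns the outcome association to the exposure's
#' effect allele: identically oriented allele pairs are kept; swapped pairs
#' have the outcome effect negated and the outcome allele frequency
#' reflected; strand-complement pairs are complemented before alignment.
#' Palindromic variants (A/T or C/G) are dropped when the exposure allele
#' frequency is within `palindrome_eaf_window` of 0.5 — or unconditionally
#' when the outcome frequency is missing — because their strand orientation
#' is otherwise unverifiable; away from 0.5 the orientation is inferred
#' from frequency agreement. Instruments absent from the outcome are
#' substituted from the proxy map when possible, otherwise dropped.
#' Irreconcilable allele pairs are dropped with reason `allele_mismatch`,
#' never silently kept.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param instruments rsids to harmonize; must all be present in `exposure`.
#' @param proxies optional [proxy_map()].
#' @param palindrome_eaf_window half-width of the exposure-frequency window
#'   around 0.5 inside which palindromic SNPs are dropped (default 0.08).
#' @return A `harmonized` tibble with one row per instrument: `rsid`,
#'   `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `status` (`kept`/`flipped`/`proxied`/`dropped_palindromic`/
#'   `dropped_missing`/`dropped`), `reason`. Rows with a `dropped_*` status
#'   have `NA` outcome effects and are excluded by estimators.
#' @export
harmonize <- function(exposure, outcome, instruments, proxies = NULL,
                      palindrome_eaf_window = 0.08) {
  missing_ins <- setdiff(instruments, exposure$rsid)
  if (length(missing_ins) > 0) {
    stop("instrument(s) absent from exposure summary statistics: ",
         paste(missing_ins, collapse = ", "), call. = FALSE)
  }
  exp_df <- as.data.frame(exposure)
  out_df <- as.data.frame(outcome)

  absent <- setdiff(instruments, out_df$rsid)
  prox <- apply_proxies(outcome, absent, proxies)
  if (!is.null(prox$records)) {
    out_df <- rbind(out_df[, SUMSTATS_COLS],
                    as.data.frame(prox$records)[, SUMSTATS_COLS])
  }
  proxied_ids <- prox$report$rsid[prox$report$status == "proxied"]

  rows <- lapply(instruments, function(rs) {
    e <- exp_df[match(rs, exp_df$rsid), ]
    base <- tibble(rsid = rs, beta_exp = e$beta, se_exp = e$se,
                   eaf_exp = e$eaf, beta_out = NA_real_, se_out = NA_real_,
                   eaf_out = NA_real_, status = "dropped",
                   reason = NA_character_)
    oi <- match(rs, out_df$rsid)
    if (is.na(oi)) {
      base$status <- "dropped_missing"
      base$reason <- "absent_from_outcome_no_proxy"
      return(base)
    }
    o <- out_df[oi, ]
    if (!all(is_simple_allele(c(e$effect_allele, e$other_allele,
                                o$effect_allele, o$other_allele)))) {
      base$status <- "dropped"
      base$reason <- "indel_not_harmonizable"
      return(base)
    }
    pal <- is_palindromic(e$effect_allele, e$other_allele)
    orientation <- if (pal) {
      # allele labels cannot resolve strand for palindromic variants:
      # use allele-frequency agreement, or drop near 0.5
      if (abs(e$eaf - 0.5) < palindrome_eaf_window) {
        base$status <- "dropped_palindromic"
        base$reason <- "eaf_near_0.5"
        return(base)
      }
      if (is.na(o$eaf)) {
        base$status <- "dropped_palindromic"
        base$reason <- "outcome_eaf_missing"
        return(base)
      }
      if (align_alleles(e$effect_allele, e$other_allele,
                        o$effect_allele, o$other_allele) == "mismatch") {
        base$status <- "dropped"
        base$reason <- "allele_mismatch"
        return(base)
      }
      if ((e$eaf - 0.5) * (o$eaf - 0.5) > 0) "same" else "swap"
    } else {
      align_alleles(e$effect_allele, e$other_allele,
                    o$effect_allele, o$other_allele)
    }
    if (orientation == "mismatch") {
      base$status <- "dropped"
      base$reason <- "allele_mismatch"
      return(base)
    }
    if (orientation == "same") {
      base$beta_out <- o$beta
      base$eaf_out <- o$eaf
      base$status <- "kept"
    } else {
      base$beta_out <- -o$beta
      base$eaf_out <- 1 - o$eaf
      base$status <- "flipped"
    }
    base$se_out <- o$se
    if (rs %in% proxied_ids) base$status <- "proxied"
    base
  })
  res <- do.call(rbind, rows)
  structure(res, class = c("harmonized", class(res)),
            proxy_report = prox$report,
            exposure = attr(exposure, "trait_name"),
            outcome = attr(outcome, "trait_name"))
}

#' Rows of a harmonized set that enter estimation
#'
#' @param h a `harmonized` tibble.
#' @return The subset with status `kept`, `flipped` or `proxied`.
#' @export
harmonized_kept <- function(h) {
  h[h$status %in% c("kept", "flipped", "proxied"), , drop = FALSE]
}

#' Write a harmonization report to TSV
#'
#' @param h a `harmonized` tibble.
#' @param path output path (columns `rsid`, `status`, `reason`).
#' @return Invisibly, `path`.
#' @export
write_harmonization_report <- function(h, path) {
  write.table(as.data.frame(h)[, c("rsid", "status", "reason")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
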