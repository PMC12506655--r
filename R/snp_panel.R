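#' Construct a validated biallelic SNP panel
#'
#' A SNP panel is the list of pre-ascertained biallelic sites that scopes all
#' per-site computation in the package: bias estimation, genotype likelihoods,
#' pseudohaploid calling and the downstream estimators all operate only at
#' panel sites. Positions are 1-based (VCF convention).
#'
#' @param chrom character vector of sequence names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single upper-case bases in \code{A,C,G,T}; \code{ref != alt}
#'   row-wise.
#' @param transversions_only if \code{TRUE}, transition pairs (A/G, C/T) are
#'   rejected. Transitions are routinely excluded from ancient-DNA panels
#'   because post-mortem deamination mimics them.
#' @return A \code{data.frame} of class \code{snp_panel} with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, sorted by
#'   (\code{chrom}, \code{pos}).
#' @export
snp_panel <- function(chrom, pos, ref, alt, transversions_only = FALSE) {
  panel <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                      ref = toupper(as.character(ref)),
                      alt = toupper(as.character(alt)),
                      stringsAsFactors = FALSE)
  validate_panel(panel, transversions_only)
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  structure(panel,
            transversions_only = transversions_only,
            class = c("snp_panel", "data.frame"))
}

validate_panel <- function(panel, transversions_only) {
  bases <- c("A", "C", "G", "T")
  if (nrow(panel) == 0) return(invisible(TRUE))
  if (any(is.na(panel$pos)) || any(panel$pos < 1))
    stop("panel positions must be integers >= 1")
  bad <- !(panel$ref %in% bases) | !(panel$alt %in% bases)
  if (any(bad))
    stop("invalid alleles at row(s): ", paste(which(bad), collapse = ", "))
  same <- panel$ref == panel$alt
  if (any(same))
    stop("ref == alt at row(s): ", paste(which(same), collapse = ", "))
  key <- paste(panel$chrom, panel$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in panel: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (transversions_only) {
    tr <- is_transition(panel$ref, panel$alt)
    if (any(tr))
      stop("transition site(s) in a transversions-only panel at row(s): ",
           paste(which(tr), collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname snp_panel
#' @param a,b allele vectors.
#' @export
is_transition <- function(a, b) {
  purine <- c("A", "G")
  (a %in% purine) == (b %in% purine)
}

#' Read a SNP panel from a whitespace-delimited TSV
#'
#' Expected columns: CHROM POS REF ALT. Lines starting with \code{#} are
#' treated as comments/header and skipped.
#'
#' @param path path to the panel file.
#' @inheritParams snp_panel
#' @return A \code{\link{snp_panel}}.
#' @export
read_snp_panel <- function(path, transversions_only = FALSE) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    return(snp_panel(character(), integer(), character(), character(),
                     transversions_only))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4))
    stop("malformed panel row (expected 4 fields) at line ",
         lineno[which(nf != 4)[1]], " of ", path)
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (any(is.na(pos)))
    stop("non-integer position at line ", lineno[which(is.na(pos))[1]],
         " of ", path)
  snp_panel(m[, 1], pos, m[, 3], m[, 4], transversions_only)
}

#' Write a SNP panel as a TSV
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param path output path.
#' @export
write_snp_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  utils::write.table(as.data.frame(panel)[, c("chrom", "pos", "ref", "alt")],
                     path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter panel sites on missingness and pooled minor allele frequency
#'
#' Retains exactly the sites with missingness strictly below
#' \code{max_missing} and pooled minor allele frequency at least
#' \code{min_maf}, the post-hoc filter applied after pseudohaploid calling.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param stats per-site statistics, e.g. from
#'   \code{\link{site_stats_from_calls}}: a data.frame with columns
#'   \code{chrom}, \code{pos}, \code{missingness}, \code{maf}. Every panel
#'   site must be present.
#' @param max_missing sites with \code{missingness >= max_missing} are removed
#'   (strict "less than" retention). Default 0.5.
#' @param min_maf sites with \code{maf >= min_maf} are retained ("at least").
#'   Default 0.1.
#' @return The filtered \code{\link{snp_panel}} (a subset of the input).
#' @export
filter_sites <- function(panel, stats, max_missing = 0.5, min_maf = 0.1) {
  stopifnot(inherits(panel, "snp_panel"))
  if (nrow(panel) == 0) return(panel)
  key_p <- paste(panel$chrom, panel$pos)
  key_s <- paste(stats$chrom, stats$pos)
  idx <- match(key_p, key_s)
  if (anyNA(idx))
    stop("no site statistics for panel site(s): ",
         paste(key_p[is.na(idx)], collapse = ", "))
  miss <- stats$missingness[idx]
  maf <- stats$maf[idx]
  keep <- (miss < max_missing) & (maf >= min_maf)
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, transversions_only = attr(panel, "transversions_only"),
            class = c("snp_panel", "data.frame"))
}

#' Per-site missingness and pooled MAF from pseudohaploid calls
#'
#' Computes the statistics consumed by \code{\link{filter_sites}} from
#' pseudohaploid calls of the populations to be pooled, counting one allele
#' per retained individual (equal weight per call).
#'
#' @param calls a pseudohaploid call table from
#'   \code{\link{call_pseudohaploid}} (columns \code{individual},
#'   \code{chrom}, \code{pos}, \code{allele} with values "ref"/"alt"/NA),
#'   covering every individual x site combination.
#' @param panel a \code{\link{snp_panel}}.
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{missingness}, \code{maf}.
#' @export
site_stats_from_calls <- function(calls, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  key_p <- paste(panel$chrom, panel$pos)
  g <- factor(paste(calls$chrom, calls$pos), levels = key_p)
  n_ind <- length(unique(calls$individual))
  n_called <- tapply(!is.na(calls$allele), g, sum, default = 0L)
  n_ref <- tapply(!is.na(calls$allele) & calls$allele == "ref", g, sum,
                  default = 0L)
  f_ref <- ifelse(n_called > 0, n_ref / n_called, NA_real_)
  data.frame(chrom = panel$chrom, pos = panel$pos,
             missingness = 1 - as.numeric(n_called) / n_ind,
             maf = pmin(f_ref, 1 - f_ref),
             row.names = NULL)
}
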