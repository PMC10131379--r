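#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated summary-statistics table into a validated
#' [GwasSummary-class].  The canonical header is `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`;
#' other dialects are ingested by supplying `column_map`.  Alleles are
#' upper-cased; rows with indel/multi-character alleles, non-positive
#' standard errors, frequencies outside \[0, 1\], p-values outside (0, 1]
#' or missing mandatory fields are dropped and counted (see the
#' `nDropped` slot), mirroring filter-based quality control of real
#' summary files.
#'
#' @param path file path of a delimited table with a header row.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(snp_id = "rsid", pvalue = "p")`; unmapped
#'   canonical names are looked up verbatim.
#' @param trait_name,trait_type,n_total,n_cases trait metadata (see
#'   [GwasSummary()]).
#' @param sep field separator (default tab).
#' @return A [GwasSummary-class] object.
#' @examples
#' g <- GwasSummary(data.frame(
#'   snp_id = "rs1", chrom = "1", pos = 100L, effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.02, se = 0.01,
#'   pvalue = 0.045, n = 1e4), traitName = "LDL")
#' f <- tempfile(fileext = ".tsv")
#' writeGwas(g, f)
#' identical(variants(readGwas(f, trait_name = "LDL")), variants(g))
#' @export
readGwas <- function(path, column_map = NULL, trait_name = "trait",
                     trait_type = c("quantitative", "binary"),
                     n_total = NA_real_, n_cases = NA_real_, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", check.names = FALSE,
                           colClasses = NA)
  if (nrow(raw) == 0 && ncol(raw) == 0)
    stop("empty file: ", path)
  cols <- GWAS_COLUMNS
  src <- stats::setNames(cols, cols)
  if (!is.null(column_map)) src[names(column_map)] <- column_map
  missing_cols <- src[!src %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  v <- data.frame(
    snp_id = as.character(raw[[src["snp_id"]]]),
    chrom = as.character(raw[[src["chrom"]]]),
    pos = as.integer(raw[[src["pos"]]]),
    effect_allele = toupper(as.character(raw[[src["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[src["other_allele"]]])),
    eaf = as.numeric(raw[[src["eaf"]]]),
    beta = as.numeric(raw[[src["beta"]]]),
    se = as.numeric(raw[[src["se"]]]),
    pvalue = as.numeric(raw[[src["pvalue"]]]),
    n = as.numeric(raw[[src["n"]]]),
    stringsAsFactors = FALSE
  )
  ok <- validVariantRows(v)
  ok[is.na(ok)] <- FALSE
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message("readGwas: dropped ", n_drop, " invalid row(s) from ", basename(path))
  v <- v[ok, , drop = FALSE]
  dup <- duplicated(v$snp_id)
  if (any(dup)) {
    message("readGwas: dropped ", sum(dup), " duplicate snp_id row(s)")
    n_drop <- n_drop + sum(dup)
    v <- v[!dup, , drop = FALSE]
  }
  GwasSummary(v, traitName = trait_name, traitType = trait_type,
              nTotal = n_total, nCases = n_cases, nDropped = n_drop)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Writes the canonical column order with full numeric precision (17
#' significant digits) so that [readGwas()] inverts it to within 1e-12
#' relative error.
#'
#' @param g a [GwasSummary-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeGwas <- function(g, path) {
  stopifnot(is(g, "GwasSummary"))
  v <- variants(g)
  out <- v
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    out[[col]] <- formatC(v[[col]], digits = 17, format = "g")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a pairwise LD (r-squared) table
#'
#' Accepts either a square matrix layout (header row and first column hold
#' snp ids) or a long format with three columns (snpA, snpB, r2).  Absent
#' pairs default to r-squared 0; long-format entries are mirrored to make
#' the matrix symmetric.  A square input asymmetric beyond 1e-8, entries
#' outside \[0, 1\], or a supplied diagonal entry different from 1 are
#' format errors.
#'
#' @param path file path (tab-separated).
#' @return An [LDMatrix-class] object.
#' @export
readLdMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  long_format <- length(header) == 3 &&
    !any(duplicated(header)) &&
    tolower(header[3]) %in% c("r2", "r_squared", "rsq")
  if (long_format) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    ids <- sort(unique(c(as.character(d[[1]]), as.character(d[[2]]))))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(d))) {
      a <- as.character(d[i, 1]); b <- as.character(d[i, 2])
      r <- as.numeric(d[i, 3])
      if (a == b) {
        if (abs(r - 1) > 1e-8)
          stop("diagonal r2 entry for ", a, " must be 1, got ", r)
        next
      }
      m[a, b] <- r
      m[b, a] <- r
    }
  } else {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(d[[1]])
    m <- as.matrix(d[, -1, drop = FALSE])
    mode(m) <- "numeric"
    if (!identical(colnames(m), ids))
      stop("square LD table: header snp ids must match first column")
    dimnames(m) <- list(ids, ids)
    if (max(abs(m - t(m))) > 1e-8) stop("LD matrix asymmetric beyond 1e-8")
    m <- (m + t(m)) / 2
    if (any(abs(diag(m) - 1) > 1e-8))
      stop("LD matrix diagonal entries must equal 1")
  }
  if (any(m < -1e-12 | m > 1 + 1e-12)) stop("r2 entries must lie in [0, 1]")
  LDMatrix(m, snpIds = rownames(m))
}

#' Write an LD matrix as a square tab-separated table
#'
#' @param ld an [LDMatrix-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeLdMatrix <- function(ld, path) {
  stopifnot(is(ld, "LDMatrix"))
  m <- r2Matrix(ld)
  out <- data.frame(snp_id = rownames(m),
                    formatC(m, digits = 17, format = "g"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("snp_id", rownames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# r2 between two snp ids under the absent-pair = 0 convention
ldLookup <- function(ld, a, b) {
  ids <- ld@snpIds
  ia <- match(a, ids)
  ib <- match(b, ids)
  if (is.na(ia) || is.na(ib)) return(0)
  ld@r2[ia, ib]
}
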