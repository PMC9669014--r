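#' Read a diploid VCF into a GenotypeMatrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and encodes the GT field as
#' alternate-allele counts. Multi-allelic records are retained and flagged
#' through the per-site allele number so that [filterSites()] can remove them
#' under the biallelic criterion; genotype calls carrying an allele index
#' above 1 are set to missing. Per-site mean read depth is taken from the
#' FORMAT `DP` field when present, falling back to an INFO `DP` value.
#'
#' @param path path to a VCF file.
#' @param popMap optional named character vector (names = individual ids,
#'   values = population labels), or path to a two-column whitespace-delimited
#'   file readable by [readPopMap()]. Individuals absent from the map get
#'   population `"pop1"`.
#' @return A [GenotypeMatrix-class].
#' @export
readVCF <- function(path, popMap = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed VCF '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no variant records")
  gtChar <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gtChar)) stop("VCF has no GT field")

  alleles <- strsplit(gsub("\\|", "/", as.vector(gtChar)), "/", fixed = TRUE)
  nal <- lengths(alleles)
  called <- !is.na(as.vector(gtChar)) & vapply(alleles, function(a)
    !any(a == "."), logical(1))
  if (any(called & nal != 2L)) {
    i <- which(called & nal != 2L)[1]
    rec <- (i - 1L) %% nrow(gtChar) + 1L
    stop(sprintf("unsupported ploidy at record %d (%s:%s): diploid GT required",
                 rec, fix[rec, "CHROM"], fix[rec, "POS"]))
  }
  code <- vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (!called[i]) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (any(is.na(ai))) return(NA_integer_)
    if (any(ai > 1L)) return(NA_integer_)  # third-or-higher allele
    sum(ai)
  }, integer(1))
  gt <- matrix(code, nrow = nrow(gtChar), ncol = ncol(gtChar),
               dimnames = dimnames(gtChar))

  alt <- fix[, "ALT"]  # 1 REF allele + 1 per comma-separated ALT
  nAlleles <- ifelse(is.na(alt) | alt == ".", 1L,
                     2L + nchar(gsub("[^,]", "", alt)))

  depth <- rep(NA_real_, nrow(gt))
  dpChar <- tryCatch(vcfR::extract.gt(vcf, element = "DP"),
                     error = function(e) NULL)
  if (!is.null(dpChar)) {
    dpNum <- suppressWarnings(matrix(as.numeric(dpChar), nrow = nrow(dpChar)))
    depth <- rowMeans(dpNum, na.rm = TRUE)
    depth[is.nan(depth)] <- NA_real_
  }
  if (all(is.na(depth))) {
    infoDp <- suppressWarnings(as.numeric(sub(".*DP=([0-9.]+).*", "\\1",
                                              fix[, "INFO"])))
    hasDp <- grepl("DP=", fix[, "INFO"] %||% "")
    depth[hasDp] <- infoDp[hasDp]
  }

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ord <- order(chrom, pos)
  dup <- duplicated(paste(chrom, pos)[ord])
  if (any(dup))
    stop("duplicated site position ", paste(chrom, pos)[ord][which(dup)[1]])

  inds <- colnames(gt)
  if (is.character(popMap) && length(popMap) == 1L && file.exists(popMap))
    popMap <- readPopMap(popMap)
  pops <- if (is.null(popMap)) rep("pop1", length(inds)) else {
    p <- unname(popMap[inds])
    p[is.na(p)] <- "pop1"
    p
  }
  GenotypeMatrix(t(gt[ord, , drop = FALSE]), chrom = chrom[ord],
                 pos = pos[ord], popLabels = pops, individualIds = inds,
                 depth = depth[ord], nAlleles = nAlleles[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GenotypeMatrix as a minimal VCF 4.2 text file
#'
#' Emits GT-only records (REF `A`, ALT `T` placeholders for synthetic data);
#' site depth, when available, is stored as an INFO `DP` value so a
#' write/read round trip preserves the object.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(gm, path) {
  gt <- genotypes(gm)
  codes <- c("0/0", "0/1", "1/1")
  gtChar <- matrix("./.", nrow = nSites(gm), ncol = nIndividuals(gm))
  idx <- !is.na(t(gt))
  gtChar[idx] <- codes[t(gt)[idx] + 1L]
  dp <- siteDepth(gm)
  info <- ifelse(is.na(dp), ".", paste0("DP=", dp))
  body <- paste(siteChrom(gm), sitePos(gm), ".", "A", "T", ".", "PASS",
                info, "GT",
                apply(gtChar, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean site depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individualIds(gm)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a two-column population map (individual, population)
#' @param path whitespace-delimited text file without header.
#' @return Named character vector mapping individual id to population.
#' @export
readPopMap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write / read a folded SFS as single-line whitespace-delimited text
#'
#' The format is a comment header giving the diploid sample size (and the
#' monomorphic count when known) followed by one line of class counts for
#' minor-allele copies 0 .. n.
#'
#' @param sfs a [FoldedSFS-class].
#' @param path file path.
#' @return `writeSFS` returns `path` invisibly; `readSFS` a [FoldedSFS-class].
#' @export
writeSFS <- function(sfs, path) {
  hdr <- sprintf("# folded SFS nIndividuals=%d nMonomorphic=%s",
                 sfs@nIndividuals,
                 ifelse(is.na(sfs@nMonomorphic), "NA",
                        format(sfs@nMonomorphic, scientific = FALSE)))
  writeLines(c(hdr, paste(sfs@counts, collapse = " ")), path)
  invisible(path)
}

#' @rdname writeSFS
#' @export
readSFS <- function(path) {
  ln <- readLines(path)
  hdr <- ln[grepl("^#", ln)][1]
  n <- as.integer(sub(".*nIndividuals=(\\d+).*", "\\1", hdr))
  monoStr <- sub(".*nMonomorphic=([^ ]+).*", "\\1", hdr)
  mono <- suppressWarnings(as.numeric(monoStr))
  counts <- scan(text = ln[!grepl("^#", ln)][1], quiet = TRUE)
  FoldedSFS(counts, n, mono)
}

#' Read / write a habitat-suitability grid as plain-text matrix
#'
#' Whitespace-delimited numeric matrix; `NA` marks no-data cells. Values are
#' suitability scores in `[0, 1]`.
#'
#' @param path file path.
#' @param grid numeric matrix.
#' @return `readGrid` a numeric matrix; `writeGrid` returns `path` invisibly.
#' @export
readGrid <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' @rdname readGrid
#' @export
writeGrid <- function(grid, path) {
  utils::write.table(grid, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a host-plant survey table
#'
#' Expects a delimited text file with header columns `site`, `taxon`,
#' `available` (plants examined) and `attacked` (plants infested).
#'
#' @param path file path.
#' @param sep field separator (default any whitespace).
#' @return A data.frame with the four columns, checked for
#'   `0 <= attacked <= available`.
#' @export
readHostSurvey <- function(path, sep = "") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("site", "taxon", "available", "attacked")
  if (!all(need %in% names(tab)))
    stop("host survey must have columns: ", paste(need, collapse = ", "))
  if (any(tab$attacked < 0 | tab$attacked > tab$available))
    stop("attacked counts must satisfy 0 <= attacked <= available")
  tab[need]
}

#' Read a FilterSpec from a key = value config file
#'
#' Lines of the form `key = value` with keys matching the [FilterSpec()]
#' arguments (e.g. `mafMin = 0.03`, `mafMin = NA`, `excludeSites =
#' chr1:100,chr1:250`). Blank lines and `#` comments are ignored.
#'
#' @param path config file path.
#' @return A [FilterSpec-class].
#' @export
readFilterSpec <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    args[[key]] <- if (key == "excludeSites")
      trimws(strsplit(val, ",")[[1]]) else suppressWarnings(as.numeric(val))
  }
  do.call(FilterSpec, args)
}
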