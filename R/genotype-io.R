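#' Read genotypes from VCF or PLINK PED/MAP
#'
#' Builds a ([MarkerMap-class], [GenotypePanel-class]) pair from standard
#' files.  VCF 4.2 is parsed with \pkg{vcfR}; `|`-separated genotypes are
#' preserved as phased, `./.` as missing.  For `format = "pedmap"`,
#' `path` is the stem: `<path>.ped` and `<path>.map` are read.
#'
#' @param path file path (VCF) or PED/MAP stem.
#' @param format `"vcf"` or `"pedmap"`.
#' @return A [GenotypePanel-class] (the map is in its `map` slot).
#' @export
readGenotypes <- function(path, format = c("vcf", "pedmap")) {
  format <- match.arg(format)
  if (format == "vcf") readVcfPanel(path) else readPedMapPanel(path)
}

#' Write genotypes to VCF or PLINK PED/MAP
#'
#' @param panel a [GenotypePanel-class].
#' @param path output file (VCF) or PED/MAP stem.
#' @param format `"vcf"` or `"pedmap"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(panel, path, format = c("vcf", "pedmap")) {
  format <- match.arg(format)
  if (format == "vcf") writeVcfPanel(panel, path)
  else writePedMapPanel(panel, path)
  invisible(path)
}

# Alleles per marker, ref = first observed, alt = others (biallelic
# expected; multi-allelic sites keep all ALT alleles comma-separated).
markerAlleles <- function(panel) {
  lapply(seq_len(nMarkers(panel)), function(j) {
    a <- unique(stats::na.omit(c(panel@a1[, j], panel@a2[, j])))
    sort(a)
  })
}

writeVcfPanel <- function(panel, path) {
  map <- panel@map
  sep <- if (panel@phased) "|" else "/"
  als <- markerAlleles(panel)
  header <- c("##fileformat=VCFv4.2",
              "##source=PositionalQTL",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individualIds(panel)),
                    collapse = "\t"))
  lines <- vapply(seq_len(nMarkers(panel)), function(j) {
    a <- als[[j]]
    ref <- if (length(a)) a[1] else "A"
    alt <- if (length(a) > 1) paste(a[-1], collapse = ",") else "."
    idx1 <- match(panel@a1[, j], a) - 1L
    idx2 <- match(panel@a2[, j], a) - 1L
    gt <- ifelse(is.na(idx1) | is.na(idx2), paste0(".", sep, "."),
                 paste0(idx1, sep, idx2))
    paste(c(map@chrom[j], format(map@pos[j], scientific = FALSE),
            map@name[j], ref, alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
}

readVcfPanel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (anyDuplicated(fix[, "ID"]))
    stop("duplicated marker name in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- all(grepl("\\|", gt[!is.na(gt) & gt != ".|." & gt != "./."]))
  n <- ncol(gt); m <- nrow(gt)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  for (j in seq_len(m)) {
    als <- c(fix[j, "REF"],
             if (!is.na(fix[j, "ALT"]) && fix[j, "ALT"] != ".")
               strsplit(fix[j, "ALT"], ",")[[1]])
    parts <- strsplit(gt[j, ], "[/|]")
    bad <- vapply(parts, length, integer(1)) != 2L & !is.na(gt[j, ])
    if (any(bad))
      stop(sprintf("malformed genotype record at marker %s (line %d)",
                   fix[j, "ID"], j))
    i1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    i2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    a1[, j] <- als[i1 + 1L]
    a2[, j] <- als[i2 + 1L]
  }
  rownames(a1) <- colnames(gt)
  map <- markerMap(fix[, "CHROM"], as.numeric(fix[, "POS"]),
                   name = fix[, "ID"],
                   cm = as.numeric(fix[, "POS"]) / 1e6)
  genotypePanel(map, a1, a2, phased = phased)
}

writePedMapPanel <- function(panel, stem) {
  map <- panel@map
  utils::write.table(
    data.frame(map@chrom, map@name, map@cm, map@pos),
    paste0(stem, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- individualIds(panel)
  g1 <- panel@a1; g2 <- panel@a2
  g1[is.na(g1)] <- "0"; g2[is.na(g2)] <- "0"
  geno <- matrix("", length(ids), 2L * nMarkers(panel))
  geno[, seq(1, ncol(geno), 2)] <- g1
  geno[, seq(2, ncol(geno), 2)] <- g2
  ped <- cbind("FAM", ids, "0", "0", "0", "-9", geno)
  utils::write.table(ped, paste0(stem, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

readPedMapPanel <- function(stem) {
  mp <- utils::read.table(paste0(stem, ".map"), sep = "\t",
                          col.names = c("chrom", "name", "cm", "pos"),
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  if (anyDuplicated(mp$name)) stop("duplicated marker name in ", stem, ".map")
  ped <- utils::read.table(paste0(stem, ".ped"), colClasses = "character")
  m <- nrow(mp)
  if (ncol(ped) != 6L + 2L * m)
    stop(sprintf("malformed PED: %d genotype columns for %d markers",
                 ncol(ped) - 6L, m))
  g <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- g[, seq(1, 2 * m, 2), drop = FALSE]
  a2 <- g[, seq(2, 2 * m, 2), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  dimnames(a1) <- dimnames(a2) <- NULL
  rownames(a1) <- ped[, 2]
  map <- markerMap(mp$chrom, mp$pos, name = mp$name, cm = mp$cm)
  genotypePanel(map, a1, a2, phased = FALSE)
}

#' Read / write a pedigree TSV
#'
#' Columns `id`, `sire`, `dam`, `sex`; missing parents are empty or `NA`
#' (founders).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPedigree <- function(path) {
  ped <- utils::read.delim(path, colClasses = "character")
  ped$sire[ped$sire == ""] <- NA
  ped$dam[ped$dam == ""] <- NA
  checkPedigree(ped)
  ped
}

#' @rdname readPedigree
#' @param ped pedigree data.frame.
#' @export
writePedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write a phenotype TSV
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) utils::read.delim(path)

#' @rdname readPhenotypes
#' @param phen phenotype data.frame.
#' @export
writePhenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
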