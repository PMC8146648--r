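# File formats: phased-SNV VCF, SV VCF (SVTYPE/SVLEN/END), BED tracks and
# TSV tables.  VCF parsing goes through vcfR, BED through rtracklayer;
# writers emit plain VCF 4.2 text (the records carry package-specific INFO
# fields).

.needs <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this I/O function")
}

#' Write phased haplotypes as VCF 4.2
#'
#' REF is the ancestral allele (A), ALT the derived allele (T); genotypes
#' are phased with "|"; the INFO field carries AA (ancestral allele).  The
#' generating seed, when given, is recorded in the header.
#'
#' @param haps a \linkS4class{HaplotypeMatrix}
#' @param path output file
#' @param chrom chromosome name
#' @param seed optional seed recorded in the header
#' @return invisibly, the path
#' @export
writeHaplotypeVCF <- function(haps, path, chrom = "chr1", seed = NULL) {
  m <- hapMatrix(haps)
  ids <- sampleIds(haps)
  uniq <- unique(ids)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(seed)) hdr <- c(hdr, sprintf("##svadapt_seed=%d", seed))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", uniq),
                      collapse = "\t"))
  rows <- vapply(seq_len(ncol(m)), function(s) {
    gts <- vapply(uniq, function(id) {
      hp <- m[ids == id, s]
      paste0(hp[1], "|", hp[2])
    }, character(1))
    paste(c(chrom, format(positions(haps)[s], scientific = FALSE),
            sprintf("snv%06d", s), "A", "T", ".", "PASS", "AA=A", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Expects phased biallelic genotypes; alleles matching the AA INFO field
#' (or REF when absent) are coded 0.
#'
#' @param path VCF file
#' @param populations optional named vector sample -> population
#' @param rate recombination rate for the default genetic map
#' @return a \linkS4class{HaplotypeMatrix}
#' @export
readHaplotypeVCF <- function(path, populations = NULL, rate = 1e-8) {
  .needs("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.numeric(vcfR::getPOS(v))
  o <- order(pos)
  gt <- gt[o, , drop = FALSE]
  pos <- pos[o]
  samples <- colnames(gt)
  hapList <- lapply(samples, function(s) {
    parts <- strsplit(gt[, s], "[|/]")
    rbind(as.integer(vapply(parts, `[`, character(1), 1)),
          as.integer(vapply(parts, `[`, character(1), 2)))
  })
  haps <- do.call(rbind, hapList)
  ids <- rep(samples, each = 2)
  pops <- if (is.null(populations)) rep("pop1", length(ids))
    else unname(populations[ids])
  HaplotypeMatrix(haps, pos, samples = ids, populations = pops,
                  rate = rate)
}

#' Write an SV callset or catalog as VCF 4.2
#'
#' INFO carries SVTYPE, SVLEN, END and, for catalogs, the carrier count.
#'
#' @param x a call data.frame (sample, chrom, start, end, svtype, length)
#'   or an \linkS4class{SVCatalog} (representative loci are written)
#' @param path output file
#' @return invisibly, the path
#' @export
writeSVVCF <- function(x, path) {
  if (is(x, "SVCatalog")) {
    mc <- mcols(svLoci(x))
    df <- data.frame(chrom = as.character(seqnames(svLoci(x))),
                     start = start(svLoci(x)), end = end(svLoci(x)),
                     svtype = as.character(mc$svtype), length = mc$svlen,
                     id = mc$locus_id, extra = sprintf(";NCARRIER=%d",
                                                       mc$n_carriers))
  } else {
    df <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                     svtype = x$svtype, length = x$length,
                     id = sprintf("call%05d", seq_len(nrow(x))),
                     extra = "")
  }
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(df$chrom), ">"),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=NCARRIER,Number=1,Type=Integer,Description=\"Carrier samples\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  rows <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d%s",
                  df$chrom, as.integer(df$start), df$id, df$svtype,
                  df$svtype,
                  as.integer(ifelse(df$svtype == "DEL", -abs(df$length),
                                    abs(df$length))),
                  as.integer(df$end), df$extra)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an SV VCF (SVTYPE/SVLEN/END INFO fields) into a call data.frame
#' @param path VCF file
#' @param sample sample id to assign to the calls
#' @return data.frame(sample, chrom, start, end, svtype, length)
#' @export
readSVVCF <- function(path, sample = "sample1") {
  .needs("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  info <- fix[, "INFO"]
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    sub(paste0(key, "="), "", m)
  }
  data.frame(sample = sample, chrom = fix[, "CHROM"],
             start = as.numeric(fix[, "POS"]),
             end = as.numeric(grab("END")),
             svtype = grab("SVTYPE"),
             length = abs(as.numeric(grab("SVLEN"))))
}

#' Write a GRanges track as BED (0-based half-open)
#' @param gr a GRanges; the first mcol (if any) becomes the name column
#' @param path output file
#' @return invisibly, the path
#' @export
writeBED <- function(gr, path) {
  .needs("rtracklayer")
  if (ncol(mcols(gr)) >= 1) {
    names(mcols(gr))[1] <- "name"
    mcols(gr) <- mcols(gr)[, "name", drop = FALSE]
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED track into a GRanges (1-based inclusive internally)
#' @param path BED file
#' @return GRanges; the BED name column (if any) is kept as mcol
#'   \code{class}
#' @export
readBED <- function(path) {
  .needs("rtracklayer")
  gr <- rtracklayer::import(path, format = "BED")
  if ("name" %in% names(mcols(gr)))
    names(mcols(gr))[names(mcols(gr)) == "name"] <- "class"
  gr
}

#' Read a sample panel TSV (sample, population, dataset[, altitude])
#' @param path TSV file with a header line
#' @return data.frame
#' @export
readPanel <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
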