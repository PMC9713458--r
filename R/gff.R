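#' Count genes overlapping an interval
#'
#' Counts features of type `gene` in a GFF3 file whose span overlaps the
#' 1-based inclusive query interval by at least 1 bp, optionally
#' restricted to a biotype attribute value (e.g.
#' `biotype = "protein_coding"`, matched against the `gene_biotype` /
#' `biotype` / `so_term_name` attributes when present). Lines that do
#' not have nine tab-separated fields are skipped with a warning before
#' parsing.
#'
#' @param gff_path path to a GFF3 file.
#' @param chrom,start_bp,end_bp query interval (1-based, inclusive).
#' @param biotype optional biotype filter.
#' @return `list(count =, genes =)` where `genes` are feature names
#'   (`Name` attribute, falling back to `ID`).
#' @export
count_genes_in_interval <- function(gff_path, chrom, start_bp, end_bp,
                                    biotype = NULL) {
  if (!file.exists(gff_path)) stop("cannot read GFF file: ", gff_path)
  if (end_bp < start_bp) stop("end_bp must be >= start_bp")
  lines <- readLines(gff_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- body & nfield != 9L
  if (any(bad)) {
    warning(sum(bad), " malformed GFF line(s) skipped")
    lines <- lines[!bad]
  }
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  gr <- rtracklayer::import(tf, format = "gff3")
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (!is.null(biotype)) {
    bt <- rep(NA_character_, length(genes))
    for (col in c("gene_biotype", "biotype", "so_term_name"))
      if (col %in% names(S4Vectors::mcols(genes))) {
        v <- as.character(S4Vectors::mcols(genes)[[col]])
        bt[is.na(bt)] <- v[is.na(bt)]
      }
    genes <- genes[!is.na(bt) & bt == biotype]
  }
  query <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(start_bp, end_bp))
  hits <- IRanges::subsetByOverlaps(genes, query)
  nm <- S4Vectors::mcols(hits)
  name <- if ("Name" %in% names(nm) && !all(is.na(nm$Name)))
    as.character(nm$Name) else as.character(nm$ID)
  list(count = length(hits), genes = name)
}
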