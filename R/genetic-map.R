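#' Construct a genetic map
#'
#' A genetic map is a set of per-chromosome anchors linking physical
#' position (bp, 1-based) to genetic position (cM). Between anchors the
#' map is interpolated piecewise-linearly; beyond the terminal anchors it
#' is extrapolated as constant. Anchors must be strictly increasing in
#' both coordinates within each chromosome, with at least two anchors
#' per chromosome.
#'
#' @param chrom chromosome name per anchor.
#' @param pos physical position in bp (1-based).
#' @param cM genetic position in centimorgans.
#' @return A `genetic_map` data frame with columns `chrom`, `pos`, `cM`.
#' @examples
#' gmap <- genetic_map("chr2L", c(1, 1e6), c(0, 2))
#' map_cm(gmap, "chr2L", 5e5)
#' @export
genetic_map <- function(chrom, pos, cM) {
  m <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  cM = as.numeric(cM), stringsAsFactors = FALSE)
  if (anyNA(m)) stop("genetic map contains missing values")
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  for (ch in unique(m$chrom)) {
    a <- m[m$chrom == ch, ]
    if (nrow(a) < 2)
      stop("chromosome '", ch, "' needs at least 2 map anchors")
    if (any(diff(a$pos) <= 0) || any(diff(a$cM) <= 0))
      stop("map anchors for '", ch,
           "' must be strictly increasing in bp and cM")
  }
  rownames(m) <- NULL
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Read a genetic map from TSV
#'
#' Expects a tab-separated file with header `chrom pos cM`.
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
load_genetic_map <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "cM")
  if (!all(need %in% names(m)))
    stop("genetic map file must have columns: ", paste(need, collapse = " "))
  genetic_map(m$chrom, m$pos, m$cM)
}

#' @rdname load_genetic_map
#' @param map a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  write.table(as.data.frame(unclass(map))[c("chrom", "pos", "cM")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

map_chroms <- function(map) unique(map$chrom)

map_span_cm <- function(map, chrom) {
  a <- map[map$chrom == chrom, ]
  if (nrow(a) == 0) stop("chromosome '", chrom, "' absent from genetic map")
  range(a$cM)
}

#' Interpolate genetic position
#'
#' `map_cm()` converts bp to cM; `map_bp()` converts cM back to bp. Both
#' are piecewise linear between anchors with constant extrapolation
#' beyond the terminal anchors.
#'
#' @param map a [genetic_map()].
#' @param chrom single chromosome name.
#' @param pos,cM positions to convert (vectorized).
#' @return Numeric vector of converted coordinates.
#' @export
map_cm <- function(map, chrom, pos) {
  a <- map[map$chrom == chrom, ]
  if (nrow(a) == 0) stop("chromosome '", chrom, "' absent from genetic map")
  approx(a$pos, a$cM, xout = pos, rule = 2)$y
}

#' @rdname map_cm
#' @export
map_bp <- function(map, chrom, cM) {
  a <- map[map$chrom == chrom, ]
  if (nrow(a) == 0) stop("chromosome '", chrom, "' absent from genetic map")
  approx(a$cM, a$pos, xout = cM, rule = 2)$y
}
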