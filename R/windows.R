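#' Build the sliding window grid
#'
#' Windows of `window_cm` centimorgans advance in `step_cm` increments
#' along each chromosome's genetic map. The first center sits at the
#' chromosome's first mapped cM plus half a window; centers advance by
#' the step for as long as the window's end does not pass the
#' chromosome's last mapped cM. Chromosomes shorter than one window get
#' zero windows, with a warning.
#'
#' @param map a [genetic_map()].
#' @param window_cm window size in cM.
#' @param step_cm step between window centers in cM.
#' @return A `window_grid` data frame: `chrom`, `center_cM`, `start_cM`,
#'   `end_cM`, `center_bp` (inverse map interpolation).
#' @examples
#' gmap <- genetic_map("c1", c(1, 15e5), c(0, 3))
#' nrow(build_window_grid(gmap))  # 31 windows on a 3 cM chromosome
#' @export
build_window_grid <- function(map, window_cm = 1.5, step_cm = 0.05) {
  if (!(window_cm > step_cm && step_cm > 0))
    stop("need window_cm > step_cm > 0")
  per_chrom <- lapply(map_chroms(map), function(ch) {
    span <- map_span_cm(map, ch)
    k <- floor((diff(span) - window_cm) / step_cm + 1e-9)
    if (k < 0) {
      warning("chromosome '", ch, "' (", diff(span),
              " cM) is shorter than one window; no windows built")
      return(NULL)
    }
    centers <- span[1] + window_cm / 2 + step_cm * (0:k)
    data.frame(chrom = ch,
               center_cM = centers,
               start_cM = centers - window_cm / 2,
               end_cM = centers + window_cm / 2,
               center_bp = map_bp(map, ch, centers))
  })
  g <- do.call(rbind, per_chrom)
  if (is.null(g))
    g <- data.frame(chrom = character(), center_cM = numeric(),
                    start_cM = numeric(), end_cM = numeric(),
                    center_bp = numeric())
  attr(g, "window_cm") <- window_cm
  attr(g, "step_cm") <- step_cm
  class(g) <- c("window_grid", "data.frame")
  g
}
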