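#' Van der Waals radii tables
#'
#' Named tables of van der Waals radii (in angstrom) used to dress atoms at
#' load time. The default `"heavy4"` table is a united-atom set for the four
#' heavy elements found in standard amino acids (C 1.87, N 1.65, O 1.40,
#' S 1.85); hydrogens, usually absent from crystal structures, are stripped at
#' load and their volume is absorbed into the heavy-atom radii.
#'
#' @param name Table name; currently `"heavy4"` (default) or `"bondi"`.
#' @return Named numeric vector of radii in angstrom, with attribute
#'   `radii_table` recording the table name (echoed in reports).
#' @examples
#' vdw_radii()["C"]
#' @export
vdw_radii <- function(name = c("heavy4", "bondi")) {
  name <- match.arg(name)
  tab <- switch(name,
    heavy4 = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85),
    bondi  = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  )
  attr(tab, "radii_table") <- name
  tab
}

# Assign radii to an element vector; unknown elements fall back to
# `default_radius` or raise an error naming the offenders.
assign_radii <- function(elements, radii = vdw_radii(), default_radius = NULL) {
  r <- unname(radii[elements])
  missing <- is.na(r)
  if (any(missing)) {
    if (is.null(default_radius)) {
      stopf("no van der Waals radius for element(s): %s (supply `default_radius` or extend the radii table)",
            paste(unique(elements[missing]), collapse = ", "))
    }
    r[missing] <- default_radius
  }
  r
}
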