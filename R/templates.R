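#' Reference idealized infarct sheet
#'
#' The 4 x 4 cm sheet at 200 um spacing (40,000 quadrilateral elements) with
#' two semicircular scar segments transected by a 4 mm border-zone isthmus,
#' centred in the sheet.
#'
#' @param size_mm sheet side (mm).
#' @param h_um element spacing (um).
#' @param isthmus_width_mm channel width (mm).
#' @param scar_half_length_mm,scar_depth_mm scar segment half-extent and
#'   depth (mm).
#' @return a `tissue_grid` with scar and border-zone labels.
#' @export
infarct_template <- function(size_mm = 40, h_um = 200, isthmus_width_mm = 4,
                             scar_half_length_mm = 17, scar_depth_mm = 16) {
  add_idealized_scar(build_sheet(size_mm, h_um),
                     scar_spec(isthmus_width_mm, scar_half_length_mm,
                               scar_depth_mm))
}

#' Scaled-down infarct sheet for fast experiments
#'
#' A 2 x 2 cm sheet with a half-scale scar around the same 4 mm isthmus.
#' Used where the qualitative block/re-entry logic (not the absolute circuit
#' timing) is under study.
#'
#' @inheritParams infarct_template
#' @return a `tissue_grid`.
#' @export
small_infarct_template <- function(size_mm = 20, h_um = 200,
                                   isthmus_width_mm = 4,
                                   scar_half_length_mm = 7,
                                   scar_depth_mm = 6) {
  add_idealized_scar(build_sheet(size_mm, h_um),
                     scar_spec(isthmus_width_mm, scar_half_length_mm,
                               scar_depth_mm))
}

#' Isthmus-traversal assay geometry
#'
#' A tall strip whose scar belt reaches the lateral edges (full-width
#' style), so the fibrotic isthmus is the only conducting path from the
#' stimulated bottom edge to the tissue above the scar. Used to test
#' whether a wavefront traverses the channel at a given fibrosis density
#' without the confound of propagation around the scar.
#'
#' @param width_mm strip width (mm).
#' @param height_mm strip height (mm).
#' @param h_um element spacing (um).
#' @param isthmus_width_mm channel width (mm).
#' @param scar_half_length_mm scar belt half-height (mm); the channel length
#'   is twice this.
#' @return a `tissue_grid`.
#' @export
traversal_template <- function(width_mm = 12, height_mm = 40, h_um = 200,
                               isthmus_width_mm = 4,
                               scar_half_length_mm = 17) {
  add_idealized_scar(build_sheet(c(width_mm, height_mm), h_um),
                     scar_spec(isthmus_width_mm, scar_half_length_mm,
                               scar_depth_mm = width_mm,
                               style = "full_width"))
}

#' Homogeneous strip for planar-wave experiments
#'
#' @param width_mm strip width (mm).
#' @param length_mm strip length in the propagation direction (mm).
#' @param h_um element spacing (um).
#' @return a `tissue_grid` of healthy tissue.
#' @export
strip_template <- function(width_mm = 6, length_mm = 40, h_um = 200) {
  build_sheet(c(width_mm, length_mm), h_um)
}
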