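# Region atlases fix node identity: the region order of the atlas is the
# column order of every thickness matrix and the row/column order of every
# association and adjacency matrix downstream.

# the 74 per-hemisphere cortical labels of the a2009s (Destrieux) parcellation
destrieux_base_names <- c(
  "G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
  "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
  "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post", "G_cingul-Post-dorsal",
  "G_cingul-Post-ventral", "G_cuneus", "G_front_inf-Opercular",
  "G_front_inf-Orbital", "G_front_inf-Triangul", "G_front_middle",
  "G_front_sup", "G_Ins_lg_and_S_cent_ins", "G_insular_short",
  "G_occipital_middle", "G_occipital_sup", "G_oc-temp_lat-fusifor",
  "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip", "G_orbital",
  "G_pariet_inf-Angular", "G_pariet_inf-Supramar", "G_parietal_sup",
  "G_postcentral", "G_precentral", "G_precuneus", "G_rectus", "G_subcallosal",
  "G_temp_sup-G_T_transv", "G_temp_sup-Lateral", "G_temp_sup-Plan_polar",
  "G_temp_sup-Plan_tempo", "G_temporal_inf", "G_temporal_middle",
  "Lat_Fis-ant-Horizont", "Lat_Fis-ant-Vertical", "Lat_Fis-post",
  "Pole_occipital", "Pole_temporal", "S_calcarine", "S_central",
  "S_cingul-Marginalis", "S_circular_insula_ant", "S_circular_insula_inf",
  "S_circular_insula_sup", "S_collat_transv_ant", "S_collat_transv_post",
  "S_front_inf", "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
  "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
  "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
  "S_oc-temp_med_and_Lingual", "S_orbital_lateral", "S_orbital_med-olfact",
  "S_orbital-H_Shaped", "S_parieto_occipital", "S_pericallosal",
  "S_postcentral", "S_precentral-inf-part", "S_precentral-sup-part",
  "S_suborbital", "S_subparietal", "S_temporal_inf", "S_temporal_sup",
  "S_temporal_transverse"
)

#' Bilateral Destrieux region atlas
#'
#' The default node set for structural covariance networks: the 74 cortical
#' regions of the Destrieux (a2009s) parcellation per hemisphere, 148 regions
#' in total, left hemisphere first. Region names carry an `lh_`/`rh_` prefix
#' and use the FreeSurfer spelling (`G_and_S_...`); readers also accept the
#' `G&S_...` dialect.
#'
#' @return A tibble with columns `region` (unique, prefixed), `name`
#'   (base label) and `hemisphere` (`"left"`/`"right"`).
#' @examples
#' destrieux_atlas()
#' @export
destrieux_atlas <- function() {
  tibble::tibble(
    region = c(paste0("lh_", destrieux_base_names),
               paste0("rh_", destrieux_base_names)),
    name = rep(destrieux_base_names, 2),
    hemisphere = rep(c("left", "right"), each = length(destrieux_base_names))
  )
}

#' Build a custom region atlas
#'
#' Mainly used to run the pipeline on reduced synthetic problems; real
#' analyses normally use [destrieux_atlas()].
#'
#' @param regions Character vector of unique region names.
#' @param hemisphere Character vector (`"left"`/`"right"`), recycled.
#' @return An atlas tibble as in [destrieux_atlas()].
#' @examples
#' region_atlas(sprintf("R%02d", 1:10))
#' @export
region_atlas <- function(regions,
                         hemisphere = rep(c("left", "right"),
                                          length.out = length(regions))) {
  atlas <- tibble::tibble(
    region = as.character(regions),
    name = sub("^(lh|rh)_", "", as.character(regions)),
    hemisphere = rep(as.character(hemisphere), length.out = length(regions))
  )
  validate_atlas(atlas)
}

validate_atlas <- function(atlas) {
  if (!all(c("region", "hemisphere") %in% names(atlas))) {
    abort("An atlas needs `region` and `hemisphere` columns.")
  }
  if (anyDuplicated(atlas$region)) {
    abort(sprintf(
      "Atlas region names must be unique; duplicated: %s",
      paste(unique(atlas$region[duplicated(atlas$region)]), collapse = ", ")
    ))
  }
  if (!all(atlas$hemisphere %in% c("left", "right"))) {
    abort("Atlas `hemisphere` must be 'left' or 'right'.")
  }
  if (is.null(atlas$name)) atlas$name <- sub("^(lh|rh)_", "", atlas$region)
  atlas
}

# accept the paper's "G&S"/"S_oc_middle&Lunatus" spelling
normalize_region_names <- function(x) {
  gsub("&", "_and_", x, fixed = TRUE)
}
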