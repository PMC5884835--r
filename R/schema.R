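# Feature schema: which measure names make up each anatomical feature set.

# The 74 cortical regions per hemisphere of the Destrieux (aparc.a2009s)
# gyral/sulcal parcellation, as named by FreeSurfer's table tools.
destrieux_regions <- c(
  "G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
  "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
  "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post",
  "G_cingul-Post-dorsal", "G_cingul-Post-ventral", "G_cuneus",
  "G_front_inf-Opercular", "G_front_inf-Orbital", "G_front_inf-Triangul",
  "G_front_middle", "G_front_sup", "G_Ins_lg_and_S_cent_ins",
  "G_insular_short", "G_occipital_middle", "G_occipital_sup",
  "G_oc-temp_lat-fusifor", "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip",
  "G_orbital", "G_pariet_inf-Angular", "G_pariet_inf-Supramar",
  "G_parietal_sup", "G_postcentral", "G_precentral", "G_precuneus",
  "G_rectus", "G_subcallosal", "G_temp_sup-G_T_transv",
  "G_temp_sup-Lateral", "G_temp_sup-Plan_polar", "G_temp_sup-Plan_tempo",
  "G_temporal_inf", "G_temporal_middle", "Lat_Fis-ant-Horizont",
  "Lat_Fis-ant-Vertical", "Lat_Fis-post", "Pole_occipital",
  "Pole_temporal", "S_calcarine", "S_central", "S_cingul-Marginalis",
  "S_circular_insula_ant", "S_circular_insula_inf",
  "S_circular_insula_sup", "S_collat_transv_ant", "S_collat_transv_post",
  "S_front_inf", "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
  "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
  "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
  "S_oc-temp_med_and_Lingual", "S_orbital_lateral", "S_orbital_med-olfact",
  "S_orbital-H_Shaped", "S_parieto_occipital", "S_pericallosal",
  "S_postcentral", "S_precentral-inf-part", "S_precentral-sup-part",
  "S_suborbital", "S_subparietal", "S_temporal_inf", "S_temporal_sup",
  "S_temporal_transverse")

# Subcortical/global measure names used to fill out the combined set.
# The source cohort's exact extra-measure list is not public; this is a
# reconstruction from FreeSurfer aseg/global naming, flagged as such, sized
# so that 3 x 148 regional measures + extras = 510 features.
aseg_extra_names <- function() {
  lateral <- c("Lateral-Ventricle", "Inf-Lat-Vent", "Cerebellum-White-Matter",
               "Cerebellum-Cortex", "Thalamus-Proper", "Caudate", "Putamen",
               "Pallidum", "Hippocampus", "Amygdala", "Accumbens-area",
               "VentralDC", "vessel", "choroid-plexus")
  c("EstimatedTotalIntraCranialVol", "BrainSegVol", "BrainSegVolNotVent",
    "MaskVol", "TotalGrayVol", "SubCortGrayVol", "CortexVol", "lhCortexVol",
    "rhCortexVol", "CorticalWhiteMatterVol", "lhCorticalWhiteMatterVol",
    "rhCorticalWhiteMatterVol", "SupraTentorialVol",
    "SupraTentorialVolNotVent", "VentricleChoroidVol",
    "MeanThickness_thickness", "lh_MeanThickness_thickness",
    "rh_MeanThickness_thickness", "WhiteSurfArea_area",
    "lh_WhiteSurfArea_area", "rh_WhiteSurfArea_area",
    "CC", "Cerebellum-Cortex", "Cerebellum-White-Matter",
    paste0("Left-", lateral), paste0("Right-", lateral),
    "3rd-Ventricle", "4th-Ventricle", "5th-Ventricle", "Brain-Stem", "CSF",
    "WM-hypointensities", "Left-WM-hypointensities",
    "Right-WM-hypointensities", "Optic-Chiasm", "CC_Posterior",
    "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior", "CC_Anterior")
}

# The 11 large-brain-region composites: total cortical volume, mean cortical
# thickness, total cortical surface area, cortical and cerebellar grey/white
# matter volumes, total subcortical grey volume, brainstem, corpus callosum,
# white-matter hypointensities.
lbr11_names <- function() {
  c("CortexVol", "MeanThickness_thickness", "WhiteSurfArea_area",
    "TotalGrayVol", "CorticalWhiteMatterVol", "Cerebellum-Cortex",
    "Cerebellum-White-Matter", "SubCortGrayVol", "Brain-Stem", "CC",
    "WM-hypointensities")
}

#' Construct a feature schema
#'
#' A `feature_schema` names every measure and defines the five anatomical
#' feature sets: the three per-region modality sets (`THICKNESS`, `AREA`,
#' `VOLUME`, one measure per cortical region each), the global composite set
#' `11LBR`, and `ALL` (the three modality sets plus all extra measures).
#' Regional measure names follow the FreeSurfer table convention
#' `<lh|rh>_<region>_<modality>`.
#'
#' @param regional_names character vector of hemisphere-prefixed cortical
#'   region labels (`lh_...`, `rh_...`), without modality suffix.
#' @param extra_names character vector of additional global/subcortical
#'   measure names entering `ALL`.
#' @param lbr_names the names forming the large-brain-region composite set;
#'   must be a subset of `extra_names`.
#' @return An object of class `feature_schema` with elements
#'   `regional_names`, `extra_names`, `modalities`, and `set_definitions`
#'   (a named list of ordered feature-name vectors).
#' @seealso [destrieux_schema()] for the packaged 510-feature schema.
#' @export
feature_schema <- function(regional_names, extra_names = character(),
                           lbr_names = character()) {
  regional_names <- as.character(regional_names)
  if (anyDuplicated(regional_names)) stop_morphid("duplicate regional names")
  if (anyDuplicated(extra_names)) stop_morphid("duplicate extra names")
  if (!all(grepl("^(lh|rh)_", regional_names))) {
    stop_morphid("regional names must be prefixed lh_/rh_")
  }
  missing_lbr <- setdiff(lbr_names, extra_names)
  if (length(missing_lbr) > 0L) {
    stop_morphid("LBR names absent from extra_names: ",
                 paste(missing_lbr, collapse = ", "))
  }
  modalities <- c("thickness", "area", "volume")
  sets <- list(
    THICKNESS = paste0(regional_names, "_thickness"),
    AREA      = paste0(regional_names, "_area"),
    VOLUME    = paste0(regional_names, "_volume"))
  sets$ALL <- c(sets$THICKNESS, sets$AREA, sets$VOLUME, extra_names)
  sets$`11LBR` <- as.character(lbr_names)
  if (anyDuplicated(sets$ALL)) {
    stop_morphid("extra names collide with regional measure names")
  }
  structure(
    list(regional_names = regional_names, extra_names = as.character(extra_names),
         modalities = modalities, set_definitions = sets),
    class = "feature_schema")
}

#' The packaged Destrieux + aseg schema (510 features)
#'
#' Returns the canonical schema used throughout: 148 Destrieux cortical
#' regions (74 per hemisphere) times three modalities (cortical thickness,
#' surface area, volume), plus 66 subcortical/global measures, totalling
#' 510 features in `ALL`. The `11LBR` set holds the 11 large-brain-region
#' composites. The extra-measure list is a reconstruction from standard
#' FreeSurfer aseg/global names (the source study's exact supplement list is
#' not public).
#'
#' @return A [feature_schema()] whose `ALL` set has exactly 510 names.
#' @export
destrieux_schema <- function() {
  regions <- c(paste0("lh_", destrieux_regions), paste0("rh_", destrieux_regions))
  feature_schema(regions, aseg_extra_names(), lbr11_names())
}

#' @export
print.feature_schema <- function(x, ...) {
  sizes <- vapply(x$set_definitions, length, integer(1L))
  cat(sprintf("feature_schema: %d cortical regions, %d extra measures\n",
              length(x$regional_names), length(x$extra_names)))
  cat("sets:", paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Feature-set names defined by a schema
#' @param schema a [feature_schema()].
#' @return Character vector of set names.
#' @export
feature_set_names <- function(schema) names(schema$set_definitions)

#' Select an anatomical feature set from a table
#'
#' Subsets a feature table to the columns of one named feature set, in
#' schema order. Rows are unchanged. The operation is idempotent: selecting
#' a set from its own result returns the same table.
#'
#' @param table a [feature_table()].
#' @param set_name one of `"11LBR"`, `"THICKNESS"`, `"AREA"`, `"VOLUME"`,
#'   `"ALL"` (or any set the schema defines).
#' @param schema a [feature_schema()]; defaults to [destrieux_schema()].
#' @return A column-subset [feature_table()].
#' @export
select_feature_set <- function(table, set_name, schema = destrieux_schema()) {
  stopifnot(inherits(table, "feature_table"), inherits(schema, "feature_schema"))
  if (!set_name %in% names(schema$set_definitions)) {
    stop_morphid("unknown feature set '", set_name, "'; available: ",
                 paste(names(schema$set_definitions), collapse = ", "))
  }
  wanted <- schema$set_definitions[[set_name]]
  absent <- setdiff(wanted, table$feature_names)
  if (length(absent) > 0L) {
    stop_morphid("feature set ", set_name, " needs columns absent from the table: ",
                 paste(utils::head(absent, 8L), collapse = ", "),
                 if (length(absent) > 8L) sprintf(" (and %d more)", length(absent) - 8L))
  }
  ft_cols(table, wanted)
}

#' Export a feature schema as JSON
#'
#' @param schema a [feature_schema()].
#' @param path output file path.
#' @export
write_schema_json <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(
    list(regional_names = schema$regional_names,
         extra_names = schema$extra_names,
         modalities = schema$modalities,
         set_definitions = schema$set_definitions),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
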