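#' Read / write study configuration as YAML
#'
#' Domain geometry ([domain_config()]), lesion settings ([lesion_config()])
#' and virtual-tumor cohorts serialize to plain YAML so a study is fully
#' described by text files.
#'
#' @param config a configuration list.
#' @param path file path.
#' @return Readers return the configuration object; writers return `path`
#'   invisibly.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_domain_config <- function(path) {
  do.call(domain_config, yaml::read_yaml(path))
}

#' @rdname write_config_yaml
#' @export
read_lesion_config <- function(path) {
  do.call(lesion_config, yaml::read_yaml(path))
}

#' @rdname write_config_yaml
#' @param cohort a list of `virtual_tumor_spec`s.
#' @export
write_cohort_yaml <- function(cohort, path) {
  yaml::write_yaml(lapply(cohort, function(s)
    list(tumor_id = s$tumor_id,
         offsets = as.list(s$offsets),
         parameters = unclass(s$parameters))), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_cohort_yaml <- function(path) {
  specs <- lapply(yaml::read_yaml(path), function(s) {
    structure(list(tumor_id = as.character(s$tumor_id),
                   parameters = do.call(model_parameters, s$parameters),
                   offsets = unlist(s$offsets)),
              class = "virtual_tumor_spec")
  })
  names(specs) <- vapply(specs, `[[`, "", "tumor_id")
  specs
}

#' Serialize the condition grid to a JSON manifest
#'
#' Maps each condition id to its acquisition settings and, when given, the
#' master seed, so every experiment cell is re-runnable in isolation.
#'
#' @param conditions data frame from [experiment_conditions()].
#' @param path output path.
#' @param seed optional master seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_condition_manifest <- function(conditions, path, seed = NULL) {
  entries <- lapply(seq_len(nrow(conditions)), function(i)
    list(snr = conditions$snr[i],
         voxel_volume = conditions$voxel_volume[i],
         tr_days = conditions$tr_days[[i]]))
  names(entries) <- conditions$condition_id
  jsonlite::write_json(list(seed = seed, conditions = entries), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
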