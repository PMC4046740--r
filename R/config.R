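#' Read a tag-specification config file
#'
#' YAML with an optional `tag:` block holding `flank`, `core_site` and
#' `max_variations`; missing keys take the package defaults.
#'
#' @param path YAML file path
#' @return a [TagSpec]
#' @export
readTagConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  tag <- if (!is.null(cfg$tag)) cfg$tag else cfg
  tagSpec(
    flank = if (!is.null(tag$flank)) tag$flank else "TCG",
    coreSite = if (!is.null(tag$core_site)) tag$core_site else "CGATCG",
    maxVariations = if (!is.null(tag$max_variations)) tag$max_variations else 1L
  )
}
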