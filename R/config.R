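#' Load an analysis configuration file
#'
#' Reads a YAML (or plain `key: value`) configuration and merges it over the
#' package defaults. The configuration collects every tunable threshold of
#' the pipeline in one place: rarity and filter thresholds, overlap
#' fractions, the extreme/middle rank cut points, fitCons class bounds,
#' connectivity class ranges, condition labels and seeds. Entries under
#' `simulation` are passed to [sim_config()].
#'
#' @param path YAML file; `NULL` returns the defaults
#'   (see `inst/extdata/default_config.yaml` for the template).
#' @return nested list of settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    maf_threshold = 0.05,
    min_hom = 1L, min_het = 3L,
    sv = list(dhffc_max = 0.70, dhbfc_min = 1.30,
              min_length = 20L, max_length = 200000L,
              reciprocal = 0.50, bnd_window = 1000L),
    expression = list(min_fraction = 0.85, min_replicates = 2L,
                      te_reciprocal = 0.50, min_ranked_samples = 10L),
    phi = list(extreme = c(0.10, 0.90), middle = c(0.40, 0.60)),
    rank_groups = list(low = c(0, 0.20), mid = c(0.40, 0.60),
                       high = c(0.80, 1.0)),
    fitcons = list(high_min = 0.2, low_max = 0.1),
    connectivity = list(high_range = c(0.80, 0.99), low_range = c(0.16, 0.77)),
    conditions = c("wet", "dry"),
    n_perm = 1000L,
    seed = 1L,
    simulation = list())
  if (is.null(path)) return(defaults)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the 'yaml' package")
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_lists(defaults, user)
}
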