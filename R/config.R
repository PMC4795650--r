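#' Run configuration
#'
#' Bundles all model and pipeline parameters with the reference defaults:
#' registration weights `alpha_u = 8e-4`, `alpha_g1 = 9e-5`,
#' `alpha_g2 = 3e-3`, `epsilon = 1e-3`; shape-prior and combination weights
#' `2e-5`; edge function with `gamma = 600`; `alpha_s1` drawn from
#' `[0.02, 0.05]`; two coupled updates of flow, indicator and sparse error
#' per frame.
#'
#' @param registration a [registration_params()].
#' @param segmentation a [segmentation_params()].
#' @param tree list: `max_level` (NULL = from image), `lip`, `grade`.
#' @param pipeline list: `updates_per_frame`, `reinit_iters`,
#'   `heaviside_band` (mollification half-width in finest cells),
#'   `prior_variant` (`"warped"` or `"unwarped"` construction of the shape
#'   prior), `init3d_mode` (`"propagate"` or `"extrude"`).
#' @param seed integer seed for any stochastic choice.
#' @return a `run_config` list.
#' @export
run_config <- function(registration = registration_params(),
                       segmentation = segmentation_params(),
                       tree = list(max_level = NULL, lip = 1.2, grade = TRUE),
                       pipeline = list(updates_per_frame = 2L,
                                       reinit_iters = 10L,
                                       heaviside_band = 1.5,
                                       prior_variant = "warped",
                                       init3d_mode = "propagate"),
                       seed = 0L) {
  tdef <- list(max_level = NULL, lip = 1.2, grade = TRUE)
  pdef <- list(updates_per_frame = 2L, reinit_iters = 10L,
               heaviside_band = 1.5, prior_variant = "warped",
               init3d_mode = "propagate")
  tree <- utils::modifyList(tdef, tree)
  pipeline <- utils::modifyList(pdef, pipeline)
  structure(list(registration = registration, segmentation = segmentation,
                 tree = tree, pipeline = pipeline, seed = as.integer(seed)),
            class = "run_config")
}

#' Read and write configurations
#'
#' Plain-text YAML serialization of a [run_config()]; the round-trip is
#' lossless (doubles are written with 17 significant digits).
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  writeLines(yaml::as.yaml(plain, precision = 17L), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cls <- class(cfg[[nm]])
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
      class(cfg[[nm]]) <- cls
    } else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

# apply `--set key.subkey=value` style overrides
apply_overrides <- function(config, sets) {
  for (s in sets) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be key=value: ", s)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    node <- config
    expr <- "config"
    for (k in keys) expr <- sprintf("%s[['%s']]", expr, k)
    eval(parse(text = sprintf("%s <- val", expr)))
  }
  config
}
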