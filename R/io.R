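#' Read a network configuration from YAML
#'
#' The YAML file may set any subset of the [bg_network_config()] arguments;
#' per-nucleus Izhikevich parameters go under `stn:`, `gpe:`, `gpi:` as
#' mappings with keys `a, b, c, d, bias` (and optional `v_peak`).  Unset
#' keys keep the package defaults.
#'
#' @param file YAML path; the bundled default lives at
#'   `system.file("extdata", "default_config.yaml", package = "bgstim")`.
#' @return a [bg_network_config()].
#' @export
read_bg_config <- function(file) {
  y <- yaml::read_yaml(file)
  for (nuc in c("stn", "gpe", "gpi")) {
    if (!is.null(y[[nuc]])) {
      p <- y[[nuc]]
      base <- nucleus_params(c(stn = "STN", gpe = "GPe", gpi = "GPi")[[nuc]])
      for (k in names(p)) base[[k]] <- p[[k]]
      y[[nuc]] <- izh_params(base$a, base$b, base$c, base$d,
                             v_peak = base$v_peak, bias = base$bias)
    }
  }
  known <- names(formals(bg_network_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(bg_network_config, y)
}

#' Write a network configuration to YAML
#'
#' @param config a [bg_network_config()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_bg_config <- function(config, file) {
  stopifnot(inherits(config, "bg_config"))
  y <- unclass(config)
  for (nuc in c("stn", "gpe", "gpi"))
    y[[nuc]] <- unclass(y[[nuc]])
  yaml::write_yaml(y, file)
  invisible(file)
}
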