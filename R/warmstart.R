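#' Shipped level-walking warm start
#'
#' The package ships an optimized design vector for level, unloaded walking
#' at the nominal target speed, found with [cma_optimize()] under the default
#' model, contact, muscle, and wiring configuration. It walks without falling
#' for the full nominal horizon and serves as the warm start for scenario
#' continuation (loads, inclines) and for the closed-loop smoke tests.
#'
#' @param file YAML file holding the design (defaults to the shipped one).
#' @param wiring the wiring the design was encoded against.
#' @return normalized design vector of length [design_length()].
#' @export
shipped_warmstart <- function(file = system.file("extdata",
                                                 "warmstart_level.yaml",
                                                 package = "reflexgait"),
                              wiring = default_wiring()) {
  y <- yaml::read_yaml(file)
  z <- as.numeric(y$design)
  if (length(z) != design_length(wiring))
    stop("warm start length does not match the wiring design length")
  z
}
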