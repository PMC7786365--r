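# shared fixtures: tiny laws and spec manipulation helpers

toy_exponential <- function(rate = 0.01, unit = "months")
  parametric_survival("exponential", scale = rate, time_unit = unit)

toy_weibull <- function(scale = 0.001, shape = 1.5, unit = "months")
  parametric_survival("weibull", scale = scale, shape = shape, time_unit = unit)

# recursively apply a function to every cea_param leaf of a spec
map_params <- function(x, f) {
  if (inherits(x, "cea_param")) return(f(x))
  if (is.list(x) && !inherits(x, "model_config"))
    for (nm in names(x)) x[[nm]] <- map_params(x[[nm]], f)
  x
}

# collapse every parameter's range (and distribution) to its point estimate
collapse_spec <- function(spec) {
  map_params(spec, function(p) {
    p$low <- p$mean; p$high <- p$mean; p$dist <- "fixed"
    p
  })
}

# spec whose two arms are identical copies of the GP arm
identical_arms_spec <- function() {
  spec <- npc_model_spec()
  spec$arms$TPF <- spec$arms$GP
  spec$arms$TPF$name <- "TPF"
  spec$doses$TPF <- spec$doses$GP
  spec
}

# zero every monetary parameter, keeping probabilities and utilities
zero_cost_spec <- function() {
  spec <- npc_model_spec()
  zero <- function(node) map_params(node, function(p) { p$mean <- 0; p })
  for (a in names(spec$arms)) {
    spec$arms[[a]]$induction <- zero(spec$arms[[a]]$induction)
    spec$arms[[a]]$picc$cost$mean <- 0
    spec$arms[[a]]$ae$g12_cost$mean <- 0
    spec$arms[[a]]$ae$g34_cost$mean <- 0
    spec$arms[[a]]$pd$subsequent$mean <- 0
  }
  spec$shared$ccrt <- zero(spec$shared$ccrt)
  spec$shared$follow_up <- zero(spec$shared$follow_up)
  spec$shared$bsc$mean <- 0
  spec
}
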