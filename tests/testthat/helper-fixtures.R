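`%||%` <- function(x, y) if (is.null(x)) y else x

# Scenario runs are expensive; build them once per test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

water_mcr_run <- function() fixture("water_mcr", function() {
  ds <- generate_dataset(scenario_design("water_dilution", seed = 1))
  lr <- lod_mcr(ds, antibiotic_references())
  list(ds = ds, lod = lr)
})

spiked_mcr_run <- function() fixture("spiked_mcr", function() {
  ds <- generate_dataset(scenario_design("spiked_urine", seed = 1))
  lr <- lod_mcr(ds, antibiotic_references())
  list(ds = ds, lod = lr)
})
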