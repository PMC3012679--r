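# One full-scale pipeline run shared by the acceptance-level tests:
# synthetic world at 1 degree (seed 42), 600 records per class, four-class
# four-scenario ensembles with 200-tree forests, global maps and integrals.
pipeline_run <- function() {
  if (!is.null(.world_cache$pipeline)) return(.world_cache$pipeline)
  bathy <- gen_bathymetry(42)
  world <- gen_predictor_grids(42, bathy)
  world <- gen_stock_records(default_truth(), world, 600, seed = 42)
  classes <- c("bacteria", "meiofauna", "macrofauna", "megafauna")
  ensembles <- lapply(classes, function(cl)
    run_simulations(world$records, world, "biomass", cl, n_trees = 200, seed = 42))
  names(ensembles) <- classes
  maps <- lapply(ensembles, grid_predict, world = world)
  linear <- lapply(maps, benthicstocks:::prediction_linear)
  total <- combine_classes(maps)
  summary <- global_summary(linear, world$bathymetry)
  .world_cache$pipeline <- list(world = world, ensembles = ensembles,
                                maps = maps, linear = linear, total = total,
                                summary = summary)
  .world_cache$pipeline
}
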