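# Shared synthetic panels, generated once per test run and cached.

.panel_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .panel_cache)) {
    assign(key, force(expr), envir = .panel_cache)
  }
  get(key, envir = .panel_cache)
}

# The 500-mutant recovery panel: 5% planted small (x0.75) and 5% planted
# large (x1.3) birth-size mutants, generator defaults otherwise.
recovery_panel <- function() {
  cached("recovery", {
    spec <- synthetic_panel_spec(n_mutants = 500, n_wildtype = 10,
                                 planted = planted_outliers(25, 25),
                                 seed = 20130901)
    gen <- generate_panel(spec)
    params <- extract_panel_parameters(gen$panel)
    list(spec = spec, panel = gen$panel, truth = gen$truth,
         params = params,
         assignments = assign_categories(params))
  })
}

# A null panel of the same shape: no planted effects at all.
null_panel <- function() {
  cached("null", {
    spec <- synthetic_panel_spec(n_mutants = 500, n_wildtype = 10,
                                 seed = 415)
    gen <- generate_panel(spec)
    params <- extract_panel_parameters(gen$panel)
    list(spec = spec, panel = gen$panel, truth = gen$truth,
         params = params,
         assignments = assign_categories(params))
  })
}

# A small quick panel for structural tests.
quick_panel <- function() {
  cached("quick", {
    spec <- synthetic_panel_spec(n_mutants = 60, n_wildtype = 6,
                                 cells_per_strain = 5000,
                                 planted = planted_outliers(4, 4),
                                 seed = 99)
    gen <- generate_panel(spec)
    params <- extract_panel_parameters(gen$panel)
    list(spec = spec, panel = gen$panel, truth = gen$truth,
         params = params,
         assignments = assign_categories(params),
         phenotypes = phenotype_link(gen$truth, seed = 100))
  })
}
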