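# Shared toy-scale replicate base, built once per test session. Small
# genome (3 chromosomes, 120 founders, 120-locus panels) so that every
# structural property can be exercised in well under a second.
toy_base <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- sim_config(ne = 30, base_generations = 60,
                        map = genome_map(n_chr = 3), n_base = 120,
                        panel_size = 120, grid_step = 5)
      cache <<- replicate_base(101, sim)
    }
    cache
  }
})

toy_scheme <- function(matrix = "G_VR2", ebv = "M",
                       panel = if (matrix == "A") "none" else "M", ...) {
  scheme_config(matrix, ebv, panel, n_offspring = 120, generations = 5,
                n_init_per_sex = 20, roh_min_mb = 20, ...)
}
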