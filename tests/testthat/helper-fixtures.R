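# Fixtures built in code; nothing is read from disk except files the tests
# themselves write to tempdirs.

sphere_profile <- function(radius = 30, q = seq(0.008, 0.35, by = 0.002)) {
  x <- q * radius
  saxs_profile(q, (3 * (sin(x) - x * cos(x)) / x^3)^2,
               label = sprintf("sphere R=%g", radius))
}

exact_guinier_profile <- function(rg = 55.4, i0 = 7,
                                  q = seq(0.003, 0.05, length.out = 150)) {
  saxs_profile(q, i0 * exp(-q^2 * rg^2 / 3))
}

# small dumbbell template: full linker physics, reduced domain size
small_template <- function(n_dom = 20L, linker = 60L) {
  build_dumbbell_template(n_domain1 = n_dom, n_domain2 = n_dom,
                          linker_residues = linker)
}

# conformer set with prescribed site-to-site distances (two-bead "models")
fake_conformer_set <- function(distances) {
  out <- tibble::tibble(
    model = seq_along(distances),
    coords = lapply(distances, function(d) rbind(c(0, 0, 0), c(0, 0, d))),
    rg = distances / 2, dmax_model = distances,
    clash_energy = 0)
  class(out) <- c("conformer_set", class(out))
  out
}

two_bead_model <- function() {
  structure(list(coords = rbind(c(0, 0, 0), c(0, 0, 1)),
                 segment = factor(c("DOMAIN1", "DOMAIN2"),
                                  levels = c("DOMAIN1", "LINKER", "DOMAIN2")),
                 site1_index = 1L, site2_index = 2L,
                 bond_length = 3.8, bead_radius = 2),
            class = "bead_model")
}

# minimal PDB text with CA atoms for one chain
write_fake_pdb <- function(path, resnos, chain = "A") {
  set.seed(99)
  lines <- vapply(seq_along(resnos), function(i) {
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, resnos[i], i * 3.8, runif(1), runif(1))
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# cached default-pipeline runs shared by the acceptance tests
pipeline_cache <- new.env(parent = emptyenv())
cached_span_run <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(pipeline_cache[[key]]))
    pipeline_cache[[key]] <- span_pipeline(n_models = 5000L, seed = seed)
  pipeline_cache[[key]]
}
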