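# Small random communities built in code for property-style tests.

# random abundance + chemistry + environment for <= a handful of sites and
# species; every species present at a site is chemically sampled
make_toy_community <- function(n_sites = 4, n_species = 3, seed = 1,
                               elements = c("N", "P")) {
  set.seed(seed)
  sites <- paste0("S", seq_len(n_sites))
  species <- paste0("sp", seq_len(n_species))
  ab <- expand.grid(site = sites, species = species,
                    stringsAsFactors = FALSE)
  ab$layer_count <- sample(0:8, nrow(ab), replace = TRUE)
  # every site keeps at least one species
  for (s in sites) {
    rows <- which(ab$site == s)
    if (all(ab$layer_count[rows] == 0))
      ab$layer_count[sample(rows, 1)] <- sample(1:8, 1)
  }
  ab <- ab[ab$layer_count > 0, ]
  chem <- do.call(rbind, lapply(elements, function(el) {
    data.frame(site = ab$site, species = ab$species, element = el,
               content = round(stats::runif(nrow(ab), 0.1, 3), 4),
               stringsAsFactors = FALSE)
  }))
  env <- data.frame(site = sites,
                    rainfall = seq(700, 1000, length.out = n_sites))
  list(abundance = ab[, c("site", "species", "layer_count")],
       chemistry = as_chemistry(chem), environment = as_environment(env))
}

# write a small table to a temp CSV and return its path
write_temp_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
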