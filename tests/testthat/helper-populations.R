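# shared helpers: small synthetic populations and worked-example profiles

fx <- load_fixtures()

site1_profile <- function() nutrient_profile(fx$sites$site1)
site2_profile <- function() nutrient_profile(fx$sites$site2)

# random strictly-positive 12-part compositions (not tied to the generator)
random_compositions <- function(n, seed, kappa = 1000) {
  set.seed(seed)
  m <- matrix(exp(stats::rnorm(n * 12, 0, 1.5)), n, 12)
  m <- m * (kappa / rowSums(m))
  colnames(m) <- composition_parts()
  m
}

# small canonical population for regional/local tests
tiny_population <- function(n = 60, seed = 11, ...) {
  suppressMessages(simulate_population(generator_config(n = n, seed = seed, ...)))
}

# nutrient profile from one canonical row
row_profile_of <- function(row) cndiag:::row_profile(row)

# canonical one-row data frame from a nutrient profile
profile_row <- function(profile, id = "Q1", clone = "clone_01",
                        soil = "soil_01", location = "loc_001",
                        age = 1.0, dbh = 4.0) {
  v <- as.list(profile$values)
  names(v) <- nutrient_columns()
  cbind(data.frame(specimen_id = id, clone = clone, soil_type = soil,
                   location = location, age_yr = age, dbh_cm = dbh,
                   stringsAsFactors = FALSE),
        as.data.frame(v))
}
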