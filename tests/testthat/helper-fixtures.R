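# Shared fixtures, built in code at test time.

demo_identity <- function(first = "Anna", last = "Müller",
                          dob = "1980-03-04", sex = "F") {
  list(first_name = first, last_name = last, date_of_birth = dob, sex = sex)
}

# A registry preloaded with a few subjects; returns the handle and the
# registered records.
seeded_registry <- function(identities = list(
                              demo_identity("Anna", "Müller", "1980-03-04", "F"),
                              demo_identity("John", "Smith", "1975-11-23", "M"),
                              demo_identity("Jane", "Smyth", "1990-06-30", "F"),
                              demo_identity("Marta", "Adams", "1962-01-05", "F")),
                            config = default_config(), path = NULL) {
  reg <- registry_create(config, path = path)
  recs <- lapply(identities, function(id) {
    register_subject(reg, id, search_subjects(reg, id), actor = "fixture")
  })
  list(registry = reg, records = recs, config = config)
}

random_identity_df <- function(n, seed) {
  generate_cohort(n, duplicate_rate = 0, max_typos = 2, seed = seed)$identities
}
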