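# Fixtures built in code: random pedigrees and small record sets.

# random multi-generation pedigree; returns ped_table inputs in shuffled order
random_pedigree_frame <- function(n, n_founders = max(4, n %/% 5),
                                  seed = 1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  sex <- rep(c("M", "F"), length.out = n)
  for (i in seq.int(n_founders + 1L, n)) {
    cand <- seq_len(i - 1L)
    males <- cand[sex[cand] == "M"]
    females <- cand[sex[cand] == "F"]
    sire[i] <- sample(males, 1)
    dam[i] <- sample(females, 1)
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam,
             birth_year = 2000L + (seq_len(n) - 1L) %/% n_founders,
             sex = sex)[sample.int(n), ]
}

# minimal valid record set for one trait; all components constant except
# what the caller overrides
make_records <- function(n, trait = "FL", score = rep(0, n),
                         age_days = rep(400L, n), farm = rep(1L, n),
                         sex = rep("M", n), region = rep(1L, n),
                         birth_year = rep(2005L, n),
                         animal = as.character(seq_len(n))) {
  data.frame(animal = animal, trait = trait, score = score,
             age_days = age_days, birth_year = birth_year, farm = farm,
             birth_month = 1L, sex = sex, weaning_farm = farm,
             yearling_farm = farm, weaning_mgmt = 1L, yearling_mgmt = 1L,
             region = region, yearling_weight = NA_real_,
             stringsAsFactors = FALSE)
}
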