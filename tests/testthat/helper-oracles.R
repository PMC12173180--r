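# Independent oracles and shared fixtures for the test suite.

# Atom-counting molecular-weight oracle: enumerates every atom of the methyl
# ester C[C+1]H[2(C+1)-2D]O2 and accumulates masses one atom at a time,
# independently of the closed-form engine expression.
oracle_mw <- function(carbons, double_bonds) {
  masses <- c(C = 12.011, H = 1.008, O = 15.999)
  atoms <- c(rep("C", carbons + 1),
             rep("H", 2 * (carbons + 1) - 2 * double_bonds),
             rep("O", 2))
  total <- 0
  for (a in atoms) total <- total + masses[[a]]
  total
}

# All species-row shorthand tokens of the packaged composition table.
table2_tokens <- function() {
  tab <- utils::read.csv(table2_fame_path(), check.names = FALSE,
                         colClasses = "character")
  tab$species
}

# The two packaged profiles.
table2_profiles <- function() read_fame_csv(table2_fame_path())

# Spreadsheet-style summation oracle for SV/IV/DU/density over a profile,
# written as explicit per-species loops against the atom-count MW oracle.
oracle_properties <- function(profile) {
  sv <- 0; iv <- 0; du <- 0; rho_num <- 0; wt_sum <- 0
  for (i in seq_len(nrow(profile$species))) {
    p <- profile$species$weight_percent[i]
    d <- profile$species$double_bonds[i]
    m <- oracle_mw(profile$species$carbons[i], d)
    sv <- sv + 560 * p / m
    iv <- iv + 254 * d * p / m
    du <- du + p * (if (d == 1) 1 else if (d >= 2) 2 else 0)
    rho_num <- rho_num + p * (0.8463 + 4.9 / m + 0.0118 * d)
    wt_sum <- wt_sum + p
  }
  list(sv = sv, iv = iv, du = du, density = rho_num / wt_sum)
}

# Brute-force check of a compact letter display against the pairwise
# decisions: treatments must share at least one letter iff the pair is not
# significantly different.
letters_match_pairwise <- function(letters_out, tukey, alpha) {
  for (k in seq_len(nrow(tukey))) {
    ab <- strsplit(tukey$pair[k], "-", fixed = TRUE)[[1]]
    shares <- length(intersect(strsplit(letters_out[[ab[1]]], "")[[1]],
                               strsplit(letters_out[[ab[2]]], "")[[1]])) > 0
    if (shares == (tukey$p_adjusted[k] < alpha)) return(FALSE)
  }
  TRUE
}

# Random valid shorthand token plus its expected parsed fields.
random_token <- function() {
  carbons <- sample(2:28, 1)
  bonds <- sample(0:min(6, carbons - 1), 1)
  omega <- if (stats::runif(1) < 0.5 && bonds > 0) sample(3:9, 1) else NA
  geometry <- sample(c("", "c", "t"), 1)
  qualifier <- if (stats::runif(1) < 0.2) sample(c("alpha", "iso"), 1) else NA
  token <- sprintf("%s%d:%d", sample(c("C", ""), 1), carbons, bonds)
  if (!is.na(omega)) token <- paste0(token, sample(c("n", "ω"), 1), omega)
  token <- paste0(token, geometry)
  if (!is.na(qualifier)) token <- paste(token, qualifier)
  list(token = token, carbons = carbons, bonds = bonds, omega = omega,
       geometry = switch(geometry, c = "cis", t = "trans", "unspecified"),
       qualifier = qualifier)
}
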