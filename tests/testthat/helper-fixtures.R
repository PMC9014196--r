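# Shared fixtures and independent oracles for the test suite.

# Panmictic population with pair coalescence rate 1 (2*eta = 1), realized
# as a zero-divergence two-tip tree.
panmictic_tree <- function(two_eta = 1) {
  two_pop_tree(D = 0, eta_x = two_eta / 2)
}

# Two-population tree in scaled units: divergence Dprime in units of
# 2*eta_x generations.
scaled_two_pop <- function(Dprime, size_ratio = 1, eta_x = 1,
                           anc_ratio = 1) {
  two_pop_tree(D = Dprime * 2 * eta_x, eta_x = eta_x,
               eta_y = size_ratio * eta_x, eta_anc = anc_ratio * eta_x)
}

# ---- Independent staged-exponential enumeration oracles (panmictic, -------
# ---- 2*eta = 1, pair coalescence rate 1). ---------------------------------
# These re-derive the analytic joint-moment constants by enumerating the
# first-coalescence outcomes and using moments of independent exponentials:
# E(U) = 1/r, E(U^2) = 2/r^2 for U ~ Exp(r).

# E(t12 * t13) for three lineages, pairs {1,2}, {1,3}.
oracle_prod_3lin <- function() {
  EU <- 1 / 3; EU2 <- 2 / 9          # first event: U ~ Exp(3)
  EV <- 1; EV2 <- 2                  # second stage: V ~ Exp(1)
  # first merge (1,2) or (1,3): one time is U, the other U + V
  cross <- EU2 + EU * EV
  # first merge (2,3): t12 = t13 = U + V
  same <- EU2 + 2 * EU * EV + EV2
  (cross + cross + same) / 3
}

# E(t12 * t34) for four lineages, pairs {1,2}, {3,4}.
oracle_prod_4lin <- function() {
  EU <- 1 / 6; EU2 <- 2 / 36         # first event among 6 pairs
  EV <- 1 / 3; EV2 <- 2 / 9          # second event among 3 pairs
  EW <- 1; EW2 <- 2                  # final event
  # first merge is (1,2) [or (3,4)]: t_A = U; t_B = U + W' where W' is the
  # remaining time for the other pair among 3 lineages, E(W') = 1/3 + 2/3*1
  EWp <- 1 / 3 + 2 / 3 * 1
  cherry <- EU2 + EU * EWp
  # first merge mixed (prob 4/6), second event V among 3 pairs:
  EUV <- EU + EV; EUV2 <- (EU2 - EU^2 + EV2 - EV^2) + EUV^2
  # (a) second merge completes one pair: times (U+V) and (U+V+W)
  one <- EUV2 + EUV * EW
  # (b) second merge is the complementary mixed pair: both times U+V+W
  both <- (EUV2 - EUV^2 + EW2 - EW^2) + (EUV + EW)^2
  (cherry + cherry) / 6 + (4 / 6) * (one + one + both) / 3
}

# E(shared branch length) for pairs {1,2}, {1,3} (three lineages).
oracle_shared_3lin <- function() {
  # lineage 1 qualifies until the first event (mean 1/3); if (2,3) merged
  # first (prob 1/3), both remaining lineages qualify for an Exp(1) stage
  1 / 3 + (1 / 3) * 2 * 1
}

# E(shared branch length) for pairs {1,2}, {3,4} (four lineages).
oracle_shared_4lin <- function() {
  # nothing qualifies until a mixed merge (prob 2/3); then one lineage
  # qualifies for an Exp(3) stage; if the complementary mixed merge follows
  # (prob 1/3), two lineages qualify for an Exp(1) stage
  (2 / 3) * (1 / 3 + (1 / 3) * 2 * 1)
}

# Case-ordering probabilities for four distinct lineages, panmictic.
oracle_cases_4lin <- function() {
  c(C1 = 1 / 6,                      # exact pair A merges first
    C2 = (2 / 3) * (1 / 3),          # mixed, then A-completing merge
    C3 = (2 / 3) * (1 / 3),          # mixed, then complementary mixed
    C4 = (2 / 3) * (1 / 3),          # mixed, then B-completing merge
    C5 = (1 / 6) * (1 / 3),          # B first, then A among 3 lineages
    C6 = (1 / 6) * (2 / 3))          # B first, then a mixed merge
}

# ---- Monte Carlo comparison helpers ---------------------------------------

z_mean <- function(x, exact) (mean(x) - exact) / (stats::sd(x) / sqrt(length(x)))

z_var <- function(x, exact) {
  dev <- (x - mean(x))^2
  (stats::var(x) - exact) / (stats::sd(dev) / sqrt(length(x)))
}

z_cov <- function(x, y, exact) {
  p <- (x - mean(x)) * (y - mean(y))
  (stats::cov(x, y) - exact) / (stats::sd(p) / sqrt(length(x)))
}
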