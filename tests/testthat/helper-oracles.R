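# Independent oracles used across the suite.

# dense multivariate-normal log-density (generic, no block structure)
dmvn_log <- function(y, mu, S) {
  L <- t(chol(S))
  z <- forwardsolve(L, y - mu)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# gene-dropping Monte-Carlo IBD oracle: founders carry unique alleles,
# each non-founder inherits one random allele from each parent; the
# kinship of (i, j) is the probability that one random allele from i and
# one from j are identical by descent.  Returns the full matrix of
# estimates plus Monte-Carlo standard errors.
gene_drop_kinship <- function(ped, nrep = 20000) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  # topological order (parents before children)
  depth <- integer(n)
  repeat {
    new <- vapply(seq_len(n), function(i) {
      f <- ped$father[i]; m <- ped$mother[i]
      max(if (is.na(f)) 0L else depth[idx[[f]]] + 1L,
          if (is.na(m)) 0L else depth[idx[[m]]] + 1L)
    }, integer(1))
    if (identical(new, depth)) break
    depth <- new
  }
  ord <- order(depth)
  acc <- matrix(0, n, n)
  acc2 <- matrix(0, n, n)
  a1 <- integer(n); a2 <- integer(n)
  for (r in seq_len(nrep)) {
    next_allele <- 1L
    for (i in ord) {
      f <- ped$father[i]; m <- ped$mother[i]
      if (is.na(f)) {
        a1[i] <- next_allele; next_allele <- next_allele + 1L
      } else {
        fi <- idx[[f]]
        a1[i] <- if (runif(1) < 0.5) a1[fi] else a2[fi]
      }
      if (is.na(m)) {
        a2[i] <- next_allele; next_allele <- next_allele + 1L
      } else {
        mi <- idx[[m]]
        a2[i] <- if (runif(1) < 0.5) a1[mi] else a2[mi]
      }
    }
    ibd <- 0.25 * ((outer(a1, a1, "==") + outer(a1, a2, "==")) +
                   (outer(a2, a1, "==") + outer(a2, a2, "==")))
    acc <- acc + ibd
    acc2 <- acc2 + ibd^2
  }
  phi_hat <- acc / nrep
  v <- pmax(acc2 / nrep - phi_hat^2, 0)
  dimnames(phi_hat) <- list(ped$id, ped$id)
  se <- sqrt(v / nrep)
  dimnames(se) <- dimnames(phi_hat)
  list(phi = phi_hat, se = se)
}

# random valid pedigree of up to n members (two founders guaranteed)
random_pedigree <- function(n, fid = "R") {
  id <- paste0(fid, "_", seq_len(n))
  sex <- c("male", "female", sample(c("male", "female"), n - 2, replace = TRUE))
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  if (n >= 3) for (i in 3:n) {
    males <- which(sex[1:(i - 1)] == "male")
    females <- which(sex[1:(i - 1)] == "female")
    if (length(males) && runif(1) < 0.7) {
      father[i] <- id[males[sample.int(length(males), 1)]]
    }
    if (length(females) && runif(1) < 0.7) {
      mother[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  as_pedigree(data.frame(fid = fid, id = id, father = father,
                         mother = mother, sex = sex,
                         stringsAsFactors = FALSE))
}

# small synthetic phenotype table used by exclusion-cascade tests:
# family A of 3 (one TPOAb-positive), family B of 2, singleton family C
toy_phenotypes <- function() {
  data.frame(
    fid = c("A", "A", "A", "B", "B", "C"),
    id = paste0("i", 1:6),
    sex = c("male", "female", "male", "female", "female", "male"),
    age = c(30, 32, 50, 48, 25, 60),
    bmi = c(22, 24, 26, 23, 21, 25),
    ui = c(100, 120, 90, 110, 80, 105),
    ucr = c(1, 1.2, 0.9, 1.1, 1, 1),
    tpoab = c(5, 40, 6, 7, 8, 9),     # i2 TPOAb-positive
    tsh = c(2.1, 2.4, 3.0, 1.9, 2.2, 2.5),
    ft4 = c(1.2, 1.3, 1.1, 1.25, 1.3, 1.15),
    stringsAsFactors = FALSE)
}

# simple two-generation pedigree matching toy_phenotypes (all founders)
toy_pedigree <- function() {
  tab <- toy_phenotypes()
  as_pedigree(data.frame(fid = tab$fid, id = tab$id,
                         father = NA_character_, mother = NA_character_,
                         sex = tab$sex, stringsAsFactors = FALSE))
}

# sibship-only scenario on the latent (identity) scale: fast, clean
# designs for parameter-recovery loops
latent_scenario <- function(preset, n_families = NULL) {
  sc <- scenario_presets(preset, n_families = n_families)
  sc$covariate_effects <- list(age = 0, age2 = 0, sex = 0, bmi = 0)
  sc$trait_scale <- list(tsh = list(type = "identity"),
                         ft4 = list(type = "identity"))
  sc
}
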