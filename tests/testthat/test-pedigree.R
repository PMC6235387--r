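test_that("pedigree files are read, blocks computed, row order kept", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("FAM1 F 0 0 1", "FAM1 M 0 0 2", "FAM1 C F M 1"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$id, c("F", "M", "C"))
  expect_length(family_blocks(ped), 1)
  expect_equal(lengths(family_blocks(ped)), 3)

  # comma-delimited with header, two unrelated sib pairs -> 2 blocks of 2
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fid,id,father,mother,sex",
               "A,a1,,,M", "A,a2,,,F",
               "B,b1,0,0,male", "B,b2,0,0,female"), f2)
  ped2 <- read_pedigree(f2)
  expect_equal(lengths(family_blocks(ped2)), c(2, 2))
})

test_that("each validation failure raises its own condition class", {
  base <- data.frame(fid = "A", id = c("f", "m", "c"),
                     father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
                     sex = c("M", "F", "M"), stringsAsFactors = FALSE)
  dup <- base; dup$id[2] <- "f"
  expect_error(as_pedigree(dup), class = "thyrovc_error_duplicate_id")

  absent <- base; absent$father[3] <- "ghost"
  expect_error(as_pedigree(absent), class = "thyrovc_error_parent_missing")

  wrong <- base; wrong$father[3] <- "m"  # mother listed as father
  expect_error(as_pedigree(wrong), class = "thyrovc_error_parent_sex")

  selfp <- base; selfp$father[3] <- "c"  # child is its own father
  expect_error(as_pedigree(selfp), class = "thyrovc_error_cycle")
})

test_that("family_blocks handles extended families, singletons, empty input", {
  trios <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(fid = paste0("T", k), id = paste0("T", k, c("f", "m", "c")),
               father = c(NA, NA, paste0("T", k, "f")),
               mother = c(NA, NA, paste0("T", k, "m")),
               sex = c("M", "F", "F"), stringsAsFactors = FALSE)
  }))
  expect_equal(lengths(family_blocks(as_pedigree(trios))), c(3, 3, 3))

  five_plus_one <- data.frame(
    fid = c(rep("X", 5), "Y"),
    id = c("gf", "gm", "d", "s", "gc", "lone"),
    father = c(NA, NA, "gf", NA, "s", NA),
    mother = c(NA, NA, "gm", NA, "d", NA),
    sex = c("M", "F", "F", "M", "M", "F"), stringsAsFactors = FALSE)
  expect_equal(sort(lengths(family_blocks(as_pedigree(five_plus_one)))),
               c(1, 5))

  empty <- as_pedigree(data.frame(fid = character(), id = character(),
                                  father = character(), mother = character(),
                                  sex = character()))
  expect_equal(family_blocks(empty), list())
})

test_that("kinship matches textbook relationships", {
  po <- as_pedigree(data.frame(fid = "A", id = c("p", "q", "c"),
                               father = c(NA, NA, "p"),
                               mother = c(NA, NA, "q"),
                               sex = c("M", "F", "M")))
  k <- kinship_matrix(po)
  expect_equal(k["p", "c"], 0.25)   # parent-offspring: 2*phi = 0.5
  expect_equal(k["p", "p"], 0.5)
  expect_equal(k["p", "q"], 0)

  sibs <- as_pedigree(data.frame(fid = "A", id = c("f", "m", "s1", "s2"),
                                 father = c(NA, NA, "f", "f"),
                                 mother = c(NA, NA, "m", "m"),
                                 sex = c("M", "F", "M", "F")))
  expect_equal(kinship_matrix(sibs)["s1", "s2"], 0.25)
})

test_that("half-sib kinship agrees with the gene-dropping oracle", {
  half <- as_pedigree(data.frame(
    fid = "H", id = c("f", "m1", "m2", "h1", "h2"),
    father = c(NA, NA, NA, "f", "f"),
    mother = c(NA, NA, NA, "m1", "m2"),
    sex = c("M", "F", "F", "M", "M")))
  expect_equal(kinship_matrix(half)["h1", "h2"], 0.125)
  set.seed(11)
  gd <- gene_drop_kinship(half, nrep = 40000)
  expect_lt(abs(gd$phi["h1", "h2"] - 0.125), 3 * gd$se["h1", "h2"])
})

test_that("inbreeding propagates: child of full-sib mating has phi_ii = 0.625", {
  inc <- as_pedigree(data.frame(
    fid = "I", id = c("f", "m", "s1", "s2", "k"),
    father = c(NA, NA, "f", "f", "s1"),
    mother = c(NA, NA, "m", "m", "s2"),
    sex = c("M", "F", "M", "F", "M")))
  k <- kinship_matrix(inc)
  # phi(s1, s2) = 0.25 so phi_kk = 0.5 * (1 + 0.25)
  expect_equal(k["k", "k"], 0.625)
  set.seed(12)
  gd <- gene_drop_kinship(inc, nrep = 40000)
  expect_lt(abs(gd$phi["k", "k"] - 0.625), 3 * gd$se["k", "k"])
})

test_that("kinship is order-equivariant and 2*Phi is positive semidefinite", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    ped <- random_pedigree(n)
    k <- kinship_matrix(ped)
    perm <- sample(n)
    ped_perm <- as_pedigree(as.data.frame(ped)[perm, ])
    expect_equal(unname(kinship_matrix(ped_perm)),
                 unname(k[perm, perm]))
    expect_gte(min(eigen(2 * k, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("recursive kinship agrees with gene dropping on random pedigrees", {
  set.seed(31)
  for (rep in 1:3) {
    ped <- random_pedigree(sample(5:8, 1))
    k <- kinship_matrix(ped)
    gd <- gene_drop_kinship(ped, nrep = 20000)
    tol <- pmax(3 * gd$se, 1e-9)  # exact zeros have zero MC error
    expect_true(all(abs(k - gd$phi) <= tol))
  }
})
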