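## Pedigree ingestion, validation, family blocks, and kinship by the
## recursive tabular method.  Founders are assumed non-inbred and mutually
## unrelated; an individual with a single known parent is treated as having
## a unique unobserved founder for the unknown side, which preserves
## half-sib relationships.

ped_error <- function(class, msg) {
  stop(structure(
    class = c(class, "thyrovc_pedigree_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.norm_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  if (anyNA(out)) {
    ped_error("thyrovc_error_sex_code",
              sprintf("unrecognized sex code(s): %s",
                      paste(unique(s[is.na(out)]), collapse = ", ")))
  }
  out
}

.norm_parent <- function(p) {
  p <- trimws(as.character(p))
  p[p %in% c("", "0", "NA") | is.na(p)] <- NA_character_
  p
}

#' Construct a validated pedigree from a data frame
#'
#' @param df data frame with columns `fid`, `id`, `father`, `mother`,
#'   `sex` (extra columns, e.g. `observed`, are kept). Missing parents are
#'   encoded as `NA`, `""` or `"0"`; sex as 1/2, M/F or male/female.
#' @return an object of class `pedigree`: the normalized data frame with a
#'   `block` column giving the connected component (via parent-child
#'   edges) of each individual.
#' @details Validation enforces unique ids, parents present in the table,
#'   father male / mother female, and acyclicity. Each violation raises a
#'   distinct condition class (`thyrovc_error_duplicate_id`,
#'   `thyrovc_error_parent_missing`, `thyrovc_error_parent_sex`,
#'   `thyrovc_error_cycle`).
#' @export
as_pedigree <- function(df) {
  need <- c("fid", "id", "father", "mother", "sex")
  if (!all(need %in% names(df))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  }
  ped <- as.data.frame(df, stringsAsFactors = FALSE)
  ped$fid <- as.character(ped$fid)
  ped$id <- as.character(ped$id)
  ped$father <- .norm_parent(ped$father)
  ped$mother <- .norm_parent(ped$mother)
  ped$sex <- .norm_sex(ped$sex)
  if (is.null(ped$observed)) ped$observed <- rep(TRUE, nrow(ped))

  if (anyDuplicated(ped$id)) {
    ped_error("thyrovc_error_duplicate_id",
              sprintf("duplicate individual id(s): %s",
                      paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")))
  }
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  for (side in c("father", "mother")) {
    ref <- ped[[side]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    if (any(bad)) {
      ped_error("thyrovc_error_parent_missing",
                sprintf("%s id(s) absent from pedigree: %s", side,
                        paste(unique(ref[bad]), collapse = ", ")))
    }
    want <- if (side == "father") "male" else "female"
    there <- !is.na(ref)
    if (any(ped$sex[idx[ref[there]]] != want)) {
      ped_error("thyrovc_error_parent_sex",
                sprintf("%s reference(s) to an individual of the wrong sex", side))
    }
  }
  ped$block <- .ped_components(ped)
  .ped_depth(ped)  # errors on cycles / self-parenthood
  class(ped) <- c("pedigree", "data.frame")
  ped
}

## connected components over parent-child edges, uniting members that
## share a family id (a household is one block even without a recorded
## genetic link, e.g. a spouse pair) -- union-find
.ped_components <- function(ped) {
  n <- nrow(ped)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  idx <- seq_len(n)
  names(idx) <- ped$id
  for (i in seq_len(n)) {
    for (side in c("father", "mother")) {
      pid <- ped[[side]][i]
      if (!is.na(pid)) unite(i, idx[[pid]])
    }
  }
  for (g in split(seq_len(n), ped$fid)) {
    if (length(g) > 1) for (i in g[-1]) unite(g[1], i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## generation depth; detects cycles (incl. self-parenthood)
.ped_depth <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  depth <- rep(NA_integer_, n)
  no_parent <- is.na(ped$father) & is.na(ped$mother)
  depth[no_parent] <- 0L
  repeat {
    progressed <- FALSE
    for (i in which(is.na(depth))) {
      f <- ped$father[i]; m <- ped$mother[i]
      df_ <- if (is.na(f)) 0L else depth[idx[[f]]]
      dm <- if (is.na(m)) 0L else depth[idx[[m]]]
      if (!is.na(df_) && !is.na(dm)) {
        depth[i] <- max(df_, dm) + 1L
        progressed <- TRUE
      }
    }
    if (!anyNA(depth)) break
    if (!progressed) {
      ped_error("thyrovc_error_cycle",
                "pedigree contains a cycle (an individual is its own ancestor)")
    }
  }
  depth
}

#' Read a pedigree from delimited text
#'
#' Accepts whitespace- or comma-delimited files with five columns
#' (family id, individual id, father id, mother id, sex), a PLINK
#' `.fam`-compatible subset. A header line is detected by non-numeric
#' column names such as `fid`/`id`/`father`. Missing parents are `0` or
#' empty; sex codes 1/2, M/F or male/female.
#'
#' @param path file path.
#' @return a validated [as_pedigree()] object, row order preserved.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  toks <- tolower(trimws(strsplit(first, if (sep == ",") "," else "[ \t]+")[[1]]))
  header <- any(toks %in% c("fid", "fam", "famid", "family", "id", "iid",
                            "father", "pat", "mother", "mat", "sex"))
  df <- read.table(path, header = header, sep = sep,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("pedigree file must have at least 5 columns")
  out <- data.frame(fid = df[[1]], id = df[[2]], father = df[[3]],
                    mother = df[[4]], sex = df[[5]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 6) {
    out$observed <- !(trimws(df[[6]]) %in% c("0", "FALSE", "false"))
  }
  as_pedigree(out)
}

#' Write a pedigree to delimited text
#' @param ped pedigree object.
#' @param path output path (tab-separated, with header).
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(fid = ped$fid, id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ifelse(ped$sex == "male", "1", "2"),
                    observed = as.integer(ped$observed))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Family blocks of a pedigree
#'
#' Connected components of the parent-child graph, additionally uniting
#' individuals that share a family id (one household = one block, so a
#' spouse pair stays together), as lists of row indices into the
#' pedigree; singletons allowed. These are the units over which the
#' model covariance is block-diagonal.
#'
#' @param ped pedigree object.
#' @return list of integer index vectors (possibly empty).
#' @export
family_blocks <- function(ped) {
  if (nrow(ped) == 0) return(list())
  unname(split(seq_len(nrow(ped)), ped$block))
}

#' Kinship matrix by the recursive tabular method
#'
#' Computes kinship coefficients \eqn{\phi_{ij}} for the given pedigree
#' rows: individuals are processed ancestors-first with
#' \eqn{\phi_{ii} = 0.5 (1 + \phi(f_i, m_i))} and
#' \eqn{\phi_{ij} = 0.5 (\phi(f_i, j) + \phi(m_i, j))} for \eqn{j} not a
#' descendant of \eqn{i}; founders are taken unrelated and non-inbred,
#' and an absent parent contributes kinship 0.
#'
#' @param ped pedigree object (a whole pedigree or one family block;
#'   parents referenced by the rows must be present).
#' @param ids optional character vector: return the matrix restricted to
#'   these individuals (in the given order). Default: all rows, input order.
#' @return symmetric kinship matrix with `dimnames` the individual ids.
#'   The additive relationship matrix is `2 *` this matrix.
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  n <- nrow(ped)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  depth <- .ped_depth(ped)
  ord <- order(depth)
  idx <- seq_len(n)
  names(idx) <- ped$id
  pos <- integer(n)        # row -> position in processing order
  pos[ord] <- seq_len(n)
  phi <- matrix(0, n, n)   # indexed by processing order
  fa <- ped$father
  mo <- ped$mother
  for (k in seq_len(n)) {
    i <- ord[k]
    pf <- if (is.na(fa[i])) 0L else pos[idx[[fa[i]]]]
    pm <- if (is.na(mo[i])) 0L else pos[idx[[mo[i]]]]
    phi_fm <- if (pf > 0L && pm > 0L) phi[pf, pm] else 0
    phi[k, k] <- 0.5 * (1 + phi_fm)
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        v <- 0
        if (pf > 0L) v <- v + phi[pf, j]
        if (pm > 0L) v <- v + phi[pm, j]
        phi[k, j] <- phi[j, k] <- 0.5 * v
      }
    }
  }
  out <- phi[pos, pos, drop = FALSE]  # back to input row order
  dimnames(out) <- list(ped$id, ped$id)
  if (!is.null(ids)) {
    if (!all(ids %in% ped$id)) stop("unknown id(s) in `ids`")
    out <- out[ids, ids, drop = FALSE]
  }
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d observed), %d blocks, %d families\n",
              nrow(x), sum(x$observed), length(unique(x$block)),
              length(unique(x$fid))))
  invisible(x)
}
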