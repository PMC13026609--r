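# Relationship catalogue: pedigrees for 18 related types (degrees 1-9) plus
# unrelated. A pedigree is a data frame (id, father, mother) in topological
# order (parents precede children; founders have NA parents) together with
# the two target individuals whose pair is emitted.

new_relationship_spec <- function(name, degree, ped, targets) {
  stopifnot(length(targets) == 2, all(targets %in% ped$id))
  structure(list(name = name,
                 degree = as.integer(degree),
                 ped = ped,
                 targets = targets,
                 founders = ped$id[is.na(ped$father)]),
            class = "relationship_spec")
}

#' @export
print.relationship_spec <- function(x, ...) {
  cat(sprintf("<relationship_spec> %s (degree %s): %d individuals, %d founders; targets %s, %s\n",
              x$name, if (x$degree >= UNRELATED_ORDINAL) "unrelated" else x$degree,
              nrow(x$ped), length(x$founders), x$targets[1], x$targets[2]))
  invisible(x)
}

# -- pedigree builders --------------------------------------------------------

ped_builder <- function() {
  rows <- list()
  add <- function(id, father = NA_character_, mother = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, father = father,
                                             mother = mother,
                                             stringsAsFactors = FALSE)
    id
  }
  list(add = add, df = function() do.call(rbind, rows))
}

# Descending chain: starting from `from`, add `n` generations, each child of
# the previous individual and a fresh founder spouse. Returns the last child.
ped_chain <- function(b, from, n, prefix) {
  cur <- from
  for (g in seq_len(n)) {
    sp <- b$add(sprintf("%s_sp%d", prefix, g))
    cur <- b$add(sprintf("%s_c%d", prefix, g), father = cur, mother = sp)
  }
  cur
}

# Collateral pedigree: the targets descend from sibling (or half-sibling)
# children of a common ancestor (couple). gen_a / gen_b count generations
# from the common ancestors to each target (1 = the sibling itself).
# Degree: gen_a + gen_b - 1 for full siblings at the top, + 1 more for half.
ped_collateral <- function(name, gen_a, gen_b, half = FALSE) {
  b <- ped_builder()
  if (half) {
    anc <- b$add("anc")
    e1 <- b$add("anc_sp1"); e2 <- b$add("anc_sp2")
    sib_a <- b$add("sibA", father = anc, mother = e1)
    sib_b <- b$add("sibB", father = anc, mother = e2)
  } else {
    a1 <- b$add("anc1"); a2 <- b$add("anc2")
    sib_a <- b$add("sibA", father = a1, mother = a2)
    sib_b <- b$add("sibB", father = a1, mother = a2)
  }
  t_a <- ped_chain(b, sib_a, gen_a - 1L, "a")
  t_b <- ped_chain(b, sib_b, gen_b - 1L, "b")
  degree <- gen_a + gen_b - 1L + if (half) 1L else 0L
  new_relationship_spec(name, degree, b$df(), c(t_a, t_b))
}

# Lineal pedigree: target B is the n-th generation descendant of target A.
ped_lineal <- function(name, n) {
  b <- ped_builder()
  a1 <- b$add("anc1"); a2 <- b$add("anc2")
  child <- b$add("c1", father = a1, mother = a2)
  t_b <- ped_chain(b, child, n - 1L, "d")
  new_relationship_spec(name, n, b$df(), c(a1, t_b))
}

# Avuncular pedigree: target A is a sibling of target B's lineal ancestor
# n generations up (n = 1: uncle/aunt, degree 2; n = 2: great-uncle, degree 3).
ped_avuncular <- function(name, n) {
  b <- ped_builder()
  g1 <- b$add("g1"); g2 <- b$add("g2")
  avunc <- b$add("avunc", father = g1, mother = g2)
  sib <- b$add("sib", father = g1, mother = g2)
  t_b <- ped_chain(b, sib, n, "d")
  new_relationship_spec(name, n + 1L, b$df(), c(avunc, t_b))
}

ped_unrelated <- function() {
  b <- ped_builder()
  u1 <- b$add("u1"); u2 <- b$add("u2")
  new_relationship_spec("unrelated", UNRELATED_ORDINAL, b$df(), c(u1, u2))
}

#' Relationship catalogue
#'
#' The default catalogue of 18 related pedigree types spanning degrees 1-9,
#' plus unrelated: parent-child and full siblings (degree 1); half-siblings,
#' grandparent-grandchild and avuncular (2); first cousins,
#' great-grandparent and grand-avuncular (3); first-cousins-once-removed and
#' half-first-cousins (4); second cousins and first-cousins-twice-removed
#' (5); second-cousins-once-removed and first-cousins-thrice-removed (6);
#' third cousins and second-cousins-twice-removed (7);
#' third-cousins-once-removed (8); fourth cousins (9). The expected kinship
#' coefficient of a degree-d pedigree is 2^-(d+1).
#'
#' @return List of `relationship_spec` objects (18 related + "unrelated").
#' @export
relationship_catalogue <- function() {
  specs <- list(
    ped_lineal("parent-child", 1L),
    ped_collateral("full-siblings", 1L, 1L),
    ped_collateral("half-siblings", 1L, 1L, half = TRUE),
    ped_lineal("grandparent-grandchild", 2L),
    ped_avuncular("avuncular", 1L),
    ped_collateral("first-cousins", 2L, 2L),
    ped_lineal("great-grandparent", 3L),
    ped_avuncular("grand-avuncular", 2L),
    ped_collateral("first-cousins-once-removed", 2L, 3L),
    ped_collateral("half-first-cousins", 2L, 2L, half = TRUE),
    ped_collateral("second-cousins", 3L, 3L),
    ped_collateral("first-cousins-twice-removed", 2L, 4L),
    ped_collateral("second-cousins-once-removed", 3L, 4L),
    ped_collateral("first-cousins-thrice-removed", 2L, 5L),
    ped_collateral("third-cousins", 4L, 4L),
    ped_collateral("second-cousins-twice-removed", 3L, 5L),
    ped_collateral("third-cousins-once-removed", 4L, 5L),
    ped_collateral("fourth-cousins", 5L, 5L),
    ped_unrelated())
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Expected kinship coefficient for a degree of kinship
#'
#' @param degree Degree ordinal 1-9 (10 = unrelated).
#' @return 2^-(degree+1), or 0 for unrelated.
#' @export
expected_kinship <- function(degree) {
  ifelse(degree >= UNRELATED_ORDINAL, 0, 2^-(degree + 1))
}
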