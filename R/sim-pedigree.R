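#' Simulate a multi-generation pedigree
#'
#' Founders form generation 0 with unknown parents.  Each later generation
#' is produced by randomly pairing the animals of the previous generation
#' (a random shuffle split into mating pairs, so no animal mates with
#' itself) and giving every pair \code{offspring_per_mating} offspring.
#' The returned records are topologically ordered: both parents of every
#' non-founder appear on earlier rows.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a data frame of class \code{"pedigree"} with columns
#'   \code{animal}, \code{sire}, \code{dam} (\code{NA} = unknown) and
#'   \code{generation}.
#' @export
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 4, n_generations = 2))
simulate_pedigree <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "pedigree"))
  id_fmt <- function(i) sprintf("ID%06d", i)
  n <- cfg$n_founders
  animal <- id_fmt(seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  generation <- rep(0L, n)
  prev <- animal
  next_id <- n + 1L
  if (cfg$n_generations >= 1) {
    for (g in seq_len(cfg$n_generations)) {
      if (length(prev) < 2)
        stop("pedigree generation ", g, " has fewer than 2 candidate parents")
      shuffled <- sample(prev)
      n_mat <- floor(length(shuffled) / 2)
      cur <- character(0)
      for (m in seq_len(n_mat)) {
        s <- shuffled[2 * m - 1]
        d <- shuffled[2 * m]
        for (k in seq_len(cfg$offspring_per_mating)) {
          id <- id_fmt(next_id)
          next_id <- next_id + 1L
          animal <- c(animal, id)
          sire <- c(sire, s)
          dam <- c(dam, d)
          generation <- c(generation, g)
          cur <- c(cur, id)
        }
      }
      prev <- cur
    }
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    generation = generation, stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree
#'
#' Checks id uniqueness, topological order (parents precede offspring) and
#' that no animal is its own parent.  Unknown parents are \code{NA}.
#'
#' @param ped a pedigree data frame with columns \code{animal}, \code{sire},
#'   \code{dam}.
#' @return the pedigree, invisibly; stops with the offending record on error.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$animal))
    stop("pedigree: duplicated animal id ",
         ped$animal[duplicated(ped$animal)][1])
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    miss <- known & !(p %in% ped$animal)
    if (any(miss))
      stop("pedigree: record ", ped$animal[miss][1], " references absent ",
           col, " ", p[miss][1])
    bad <- known & pos[p] >= pos[ped$animal]
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      stop("pedigree: record ", ped$animal[bad][1],
           " is not preceded by its ", col, " ", p[bad][1],
           " (pedigree must be topologically ordered)")
  }
  invisible(ped)
}
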