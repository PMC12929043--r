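# Residue-level histone-tail contact profiling on coarse-grained frames:
# one bead per residue/nucleotide, contacts by distance cutoff, split into
# intra-nucleosome, inter-nucleosome intra-array and inter-array scopes.

.cg_roles <- c("histone-core", "tail-H3", "tail-H4", "tail-H2A(N)",
               "tail-H2B", "DNA")
.cg_scopes <- c("intra-nucleosome", "intra-array", "inter-array")

#' Construct a coarse-grained frame
#'
#' A residue-resolution bead table: one row per bead with chain, residue,
#' role, nucleosome and array labels, coordinates in Angstrom.
#'
#' @param beads Data.frame with columns `chain_id`, `residue_index`,
#'   `residue_name`, `role` (one of histone-core, tail-H3, tail-H4,
#'   tail-H2A(N), tail-H2B, DNA), `nucleosome_id`, `array_id` (defaults to 1
#'   when absent), `x`, `y`, `z` (Angstrom).
#' @return Object of class `cg_frame` (a validated data.frame).
#' @export
cg_frame <- function(beads) {
  beads <- as.data.frame(beads)
  need <- c("chain_id", "residue_index", "residue_name", "role",
            "nucleosome_id", "x", "y", "z")
  miss <- setdiff(need, names(beads))
  if (length(miss)) stop("missing bead columns: ", paste(miss, collapse = ", "))
  if (!"array_id" %in% names(beads)) beads$array_id <- 1L
  if (anyNA(beads$nucleosome_id)) stop("every bead needs a nucleosome_id")
  bad <- setdiff(unique(beads$role), .cg_roles)
  if (length(bad)) stop("unknown bead roles: ", paste(bad, collapse = ", "))
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")]))))
    stop("bead coordinates must be finite")
  dup <- duplicated(beads[, c("chain_id", "residue_index")])
  if (any(dup)) stop("residue_index must be unique within a chain")
  class(beads) <- c("cg_frame", "data.frame")
  beads
}

#' Count bead-pair contacts in a coarse-grained frame
#'
#' All bead pairs within `cutoff` Angstrom, excluding pairs on the same
#' chain separated by at most 2 residues (bonded exclusion).  Each contact
#' is labelled by scope: `intra-nucleosome` (same nucleosome),
#' `intra-array` (same array, different nucleosome) or `inter-array`.
#' The cell-list neighbour search reproduces the quadratic all-pairs scan
#' exactly.
#'
#' @param f A `cg_frame`.
#' @param cutoff Contact cutoff in Angstrom (default 7).
#' @return Data.frame with one row per contact: bead row indices `i`, `j`,
#'   `dist`, `scope`.
#' @export
count_contacts <- function(f, cutoff = 7.0) {
  stopifnot(inherits(f, "cg_frame"), cutoff > 0)
  pr <- cpp_neighbor_pairs(as.matrix(f[, c("x", "y", "z")]), cutoff)
  if (!nrow(pr))
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0),
                      scope = character(0)))
  same_chain <- f$chain_id[pr$i] == f$chain_id[pr$j]
  bonded <- same_chain &
    abs(f$residue_index[pr$i] - f$residue_index[pr$j]) <= 2
  pr <- pr[!bonded, , drop = FALSE]
  same_nuc <- f$nucleosome_id[pr$i] == f$nucleosome_id[pr$j]
  same_arr <- f$array_id[pr$i] == f$array_id[pr$j]
  scope <- ifelse(same_nuc, "intra-nucleosome",
                  ifelse(same_arr, "intra-array", "inter-array"))
  data.frame(i = pr$i, j = pr$j, dist = pr$dist, scope = scope)
}

# per-bead contact participation counts of one frame, by scope
.frame_bead_counts <- function(f, cutoff) {
  ct <- count_contacts(f, cutoff)
  m <- matrix(0, nrow(f), length(.cg_scopes),
              dimnames = list(NULL, .cg_scopes))
  for (s in .cg_scopes) {
    sel <- ct$scope == s
    if (any(sel)) {
      tab <- tabulate(c(ct$i[sel], ct$j[sel]), nbins = nrow(f))
      m[, s] <- tab
    }
  }
  m
}

#' Residue-level contact profile across frames
#'
#' For every (tail role, residue index) the mean number of contacts per
#' frame in which that residue participates (a residue touching three
#' partners counts 3), split by scope, with the SD across frames (population
#' convention, divide by n).  Frames must share an identical bead topology.
#'
#' @param frames A `cg_frame` or list of `cg_frame`s.
#' @param cutoff Contact cutoff in Angstrom.
#' @return List with `profile` (role, residue_index, scope, mean, sd),
#'   `totals` (per nucleosome x role x scope mean), `n_frames`, `cutoff`.
#' @export
contact_profile <- function(frames, cutoff = 7.0) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  if (!length(frames)) stop("at least one frame is required")
  f0 <- frames[[1]]
  topo <- f0[, c("chain_id", "residue_index", "role", "nucleosome_id",
                 "array_id")]
  for (f in frames[-1]) {
    if (!isTRUE(all.equal(topo, f[, names(topo)], check.attributes = FALSE)))
      stop("inconsistent bead topology across frames")
  }
  counts <- lapply(frames, .frame_bead_counts, cutoff = cutoff)
  nf <- length(frames)
  # per-frame per-(role, residue, scope) value: mean over chains of that role
  key <- interaction(f0$role, f0$residue_index, drop = TRUE)
  prof <- NULL
  for (s in .cg_scopes) {
    per_frame <- vapply(counts, function(m) {
      as.numeric(tapply(m[, s], key, mean))
    }, numeric(nlevels(key)))
    per_frame <- matrix(per_frame, nrow = nlevels(key))
    mu <- rowMeans(per_frame)
    sdev <- sqrt(rowMeans((per_frame - mu)^2))  # population SD
    lv <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
    prof <- rbind(prof, data.frame(role = lv[, 1],
                                   residue_index = as.integer(lv[, 2]),
                                   scope = s, mean = mu, sd = sdev))
  }
  prof <- prof[order(prof$role, prof$residue_index, prof$scope), ]
  rownames(prof) <- NULL
  # tail totals per nucleosome
  key2 <- interaction(f0$nucleosome_id, f0$role, drop = TRUE)
  totals <- NULL
  for (s in .cg_scopes) {
    per_frame <- vapply(counts, function(m) {
      as.numeric(tapply(m[, s], key2, sum))
    }, numeric(nlevels(key2)))
    per_frame <- matrix(per_frame, nrow = nlevels(key2))
    lv <- do.call(rbind, strsplit(levels(key2), ".", fixed = TRUE))
    totals <- rbind(totals, data.frame(nucleosome_id = lv[, 1],
                                       role = lv[, 2], scope = s,
                                       mean_total = rowMeans(per_frame)))
  }
  list(profile = prof, totals = totals, n_frames = nf, cutoff = cutoff)
}
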