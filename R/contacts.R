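# residue-residue contact mapping and classification

.POS_GROUP <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                   HIS = c("ND1", "NE2"))
.NEG_GROUP <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Residue contact map between two selections
#'
#' Lists residue pairs with any heavy-atom (non-hydrogen) distance within
#' the van der Waals cutoff, and classifies each contact: upgraded to
#' `salt-bridge` when oppositely charged side-chain groups (Arg/Lys/His
#' nitrogens vs Asp/Glu carboxylate oxygens) lie within the salt-bridge
#' cutoff, to `hbond-capable` when donor/acceptor heavy atoms (N/O) lie
#' within the hydrogen-bond cutoff, otherwise `vdw`.
#'
#' @param structure a [structure3d].
#' @param sel_a,sel_b disjoint selections (partner A and B).
#' @param cutoffs named numeric vector with entries `salt_bridge`
#'   (default 4.0 A), `hbond` (3.5 A) and `vdw` (4.5 A).
#' @param partners optional character pair labelling the partners.
#' @return An `interface_report`: list with `partners` and `contacts`
#'   (data.frame: residue identities, `min_distance` A, `class`).
#' @export
contact_map <- function(structure, sel_a, sel_b,
                        cutoffs = c(salt_bridge = 4.0, hbond = 3.5,
                                    vdw = 4.5),
                        partners = c("A", "B")) {
  stopifnot(inherits(structure, "structure3d"))
  ia <- .sel_idx(sel_a, structure)
  ib <- .sel_idx(sel_b, structure)
  if (length(intersect(ia, ib))) stop("selections overlap")
  at <- structure$atoms
  xyz <- coords(structure)
  heavy <- toupper(at$element) != "H"
  ia <- ia[heavy[ia]]; ib <- ib[heavy[ib]]
  if (!length(ia) || !length(ib)) {
    stop("empty heavy-atom selection for contact mapping")
  }
  rid <- function(i) paste(at$chain_id[i], at$residue_number[i],
                           at$insertion_code[i], sep = ":")
  ra <- rid(ia); rb <- rid(ib)

  # pairwise distances between the two (typically small) selections
  d <- sqrt(outer(rowSums(xyz[ia, , drop = FALSE]^2),
                  rowSums(xyz[ib, , drop = FALSE]^2), "+") -
              2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE]))
  within <- which(d <= cutoffs[["vdw"]], arr.ind = TRUE)
  if (!nrow(within)) {
    contacts <- data.frame(chain_a = character(), residue_a = integer(),
                           resname_a = character(), chain_b = character(),
                           residue_b = integer(), resname_b = character(),
                           min_distance = numeric(), class = character(),
                           stringsAsFactors = FALSE)
  } else {
    pair_key <- paste(ra[within[, 1]], rb[within[, 2]], sep = "|")
    rows <- lapply(split(seq_len(nrow(within)), pair_key), function(k) {
      i_at <- ia[within[k, 1]]; j_at <- ib[within[k, 2]]
      dk <- d[within[k, , drop = FALSE]]
      i1 <- i_at[1]; j1 <- j_at[1]
      cls <- "vdw"
      # hbond-capable: N/O vs N/O within hbond cutoff
      no_i <- toupper(at$element[i_at]) %in% c("N", "O")
      no_j <- toupper(at$element[j_at]) %in% c("N", "O")
      if (any(no_i & no_j & dk <= cutoffs[["hbond"]])) cls <- "hbond-capable"
      # salt bridge: oppositely charged side-chain groups
      chg <- function(idx) {
        rn <- at$residue_name[idx]; an <- at$atom_name[idx]
        p <- mapply(function(r, a) !is.null(.POS_GROUP[[r]]) &&
                      a %in% .POS_GROUP[[r]], rn, an)
        m <- mapply(function(r, a) !is.null(.NEG_GROUP[[r]]) &&
                      a %in% .NEG_GROUP[[r]], rn, an)
        ifelse(p, 1L, ifelse(m, -1L, 0L))
      }
      qi <- chg(i_at); qj <- chg(j_at)
      if (any(qi * qj == -1L & dk <= cutoffs[["salt_bridge"]])) {
        cls <- "salt-bridge"
      }
      data.frame(chain_a = at$chain_id[i1], residue_a = at$residue_number[i1],
                 resname_a = at$residue_name[i1],
                 chain_b = at$chain_id[j1], residue_b = at$residue_number[j1],
                 resname_b = at$residue_name[j1],
                 min_distance = min(dk), class = cls,
                 stringsAsFactors = FALSE)
    })
    contacts <- do.call(rbind, rows)
    contacts <- contacts[order(contacts$chain_a, contacts$residue_a,
                               contacts$chain_b, contacts$residue_b), ]
    rownames(contacts) <- NULL
  }
  out <- list(partners = partners, contacts = contacts, cutoffs = cutoffs)
  class(out) <- "interface_report"
  out
}

#' @export
print.interface_report <- function(x, ...) {
  cat("interface_report:", x$partners[1], "vs", x$partners[2], "-",
      nrow(x$contacts), "residue contact(s)\n")
  if (!is.null(x$buried_area)) {
    cat("  buried area:", sprintf("%.1f", x$buried_area), "A^2 (",
        attr(x$buried_area, "convention"), ")\n")
  }
  if (nrow(x$contacts)) print(x$contacts)
  invisible(x)
}

#' Full interface report (contacts + buried area)
#'
#' Convenience wrapper combining [contact_map()] and
#' [buried_surface_area()] for one chain/domain pair.
#'
#' @inheritParams contact_map
#' @param params a [sasa_params].
#' @param convention buried-area convention, see [buried_surface_area()].
#' @return An `interface_report` with an additional `buried_area` field.
#' @export
interface_report <- function(structure, sel_a, sel_b,
                             cutoffs = c(salt_bridge = 4.0, hbond = 3.5,
                                         vdw = 4.5),
                             params = sasa_params(),
                             convention = c("per-interface", "total"),
                             partners = c("A", "B")) {
  rep <- contact_map(structure, sel_a, sel_b, cutoffs, partners)
  rep$buried_area <- buried_surface_area(structure, sel_a, sel_b, params,
                                         match.arg(convention))
  rep
}
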