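# PFAS class/subclass rule cascade.
#
# The cascade runs, in fixed order: the PFAS definition filter (module 1,
# with derivative subclassing of near-misses), the silicon filter (module 2),
# the side-chain fluorinated aromatic filter (module 3), carbocycle ring
# opening (module 4), and finally the core class-subclass rules following the
# Buck/OECD taxonomy. Every parseable structure receives exactly one result.

.pfas_categories <- c(
  "not_pfas", "pfas_derivative", "silicon_pfas",
  "side_chain_fluorinated_aromatic", "aliphatic_pfas"
)

# ---- module 1: definition filter ------------------------------------------

# terminal CF3: sp3 carbon, no H, carrying >= 3 fluorines
.is_cf3 <- function(mol, i) {
  mol$atoms$symbol[i] == "C" && mol$atoms$nH[i] == 0L &&
    mol_is_sp3_carbon(mol, i) && mol_f_count(mol, i) >= 3L
}

# chain -CF2-: sp3 carbon, no H, exactly two fluorines, both remaining bonds
# to carbon
.is_chain_cf2 <- function(mol, i) {
  if (!(mol$atoms$symbol[i] == "C" && mol$atoms$nH[i] == 0L &&
    mol_is_sp3_carbon(mol, i))) {
    return(FALSE)
  }
  nb <- mol_neighbors(mol, i)
  sum(mol$atoms$symbol[nb] == "F") == 2L &&
    sum(mol$atoms$symbol[nb] == "C") == (length(nb) - 2L)  &&
    length(nb) == 4L
}

.module1_pfas <- function(mol) {
  any(vapply(seq_len(nrow(mol$atoms)), function(i) {
    .is_cf3(mol, i) || .is_chain_cf2(mol, i)
  }, logical(1)))
}

# derivative subclasses, tested in this order
.derivative_subclass <- function(mol) {
  n <- nrow(mol$atoms)
  # -F substituted by -Cl or -Br on an otherwise perfluorinated carbon
  for (i in seq_len(n)) {
    if (mol$atoms$symbol[i] == "C" && mol$atoms$nH[i] == 0L &&
      mol_is_sp3_carbon(mol, i)) {
      nb_sym <- mol$atoms$symbol[mol_neighbors(mol, i)]
      if (any(nb_sym == "F") && any(nb_sym %in% c("Cl", "Br")) &&
        all(nb_sym %in% c("F", "Cl", "Br", "C"))) {
        return("halogen_substituted")
      }
    }
  }
  # fluorinated C=C or C=O carbon (aromatic bonds are kekulized in the
  # connection table, so aromatic atoms are excluded here and handled below)
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] == 2L) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      if (mol$atoms$aromatic[a] || mol$atoms$aromatic[b]) next
      pair <- sort(mol$atoms$symbol[c(a, b)])
      if (identical(pair, c("C", "C")) || identical(pair, c("C", "O"))) {
        for (i in c(a, b)) {
          if (mol$atoms$symbol[i] == "C" && mol_f_count(mol, i) > 0) {
            return("fluorinated_unsaturated_carbon")
          }
        }
      }
    }
  }
  # fluorinated aromatic carbon
  for (i in seq_len(n)) {
    if (mol$atoms$symbol[i] == "C" && mol$atoms$aromatic[i] &&
      mol_f_count(mol, i) > 0) {
      return("fluorinated_aromatic_carbon")
    }
  }
  NA_character_
}

# ---- perfluoroalkyl chain length ------------------------------------------

# Fully fluorinated sp3 carbons: no H, >= 2 F, at most two non-fluorine
# neighbors. The chain length n is the longest path through this set.
.perfluoro_set <- function(mol) {
  deg <- mol_degree(mol)
  which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    if (!(mol$atoms$symbol[i] == "C" && mol$atoms$nH[i] == 0L &&
      mol_is_sp3_carbon(mol, i))) {
      return(FALSE)
    }
    nf <- mol_f_count(mol, i)
    nf >= 2L && (deg[i] - nf) <= 2L
  }, logical(1)))
}

.perfluoro_chain_n <- function(mol) {
  S <- .perfluoro_set(mol)
  if (length(S) == 0) return(0L)
  adj <- lapply(S, function(i) intersect(mol_neighbors(mol, i), S))
  names(adj) <- as.character(S)
  best <- 0L
  dfs <- function(v, visited) {
    visited <- c(visited, v)
    best <<- max(best, length(visited))
    for (w in adj[[as.character(v)]]) {
      if (!(w %in% visited)) dfs(w, visited)
    }
  }
  for (v in S) dfs(v, integer(0))
  best
}

# ---- structural motif helpers ---------------------------------------------

.dbl_o_neighbors <- function(mol, i) {
  nb <- mol_neighbors(mol, i)
  nb[mol$atoms$symbol[nb] == "O" &
    vapply(nb, function(j) mol_bond_order(mol, i, j) == 2L, logical(1))]
}

.hydroxyl_neighbors <- function(mol, i) {
  nb <- mol_neighbors(mol, i)
  nb[vapply(nb, function(j) {
    mol$atoms$symbol[j] == "O" && mol_bond_order(mol, i, j) == 1L &&
      mol$atoms$nH[j] >= 1L && length(mol_neighbors(mol, j)) == 1L
  }, logical(1))]
}

.ether_o_neighbors <- function(mol, i) {
  nb <- mol_neighbors(mol, i)
  nb[vapply(nb, function(j) {
    mol$atoms$symbol[j] == "O" && mol$atoms$nH[j] == 0L &&
      length(mol_neighbors(mol, j)) == 2L &&
      all(mol_bond_order(mol, j, mol_neighbors(mol, j)[1]) == 1L,
          mol_bond_order(mol, j, mol_neighbors(mol, j)[2]) == 1L)
  }, logical(1))]
}

# carboxyl carbon: C(=O)(OH)C
.carboxyl_carbons <- function(mol) {
  which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    mol$atoms$symbol[i] == "C" &&
      length(.dbl_o_neighbors(mol, i)) == 1L &&
      length(.hydroxyl_neighbors(mol, i)) == 1L &&
      sum(mol$atoms$symbol[mol_neighbors(mol, i)] == "C") == 1L
  }, logical(1)))
}

# sulfonic sulfur: S(=O)(=O)(OH)C
.sulfonic_s <- function(mol) {
  which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    mol$atoms$symbol[i] == "S" &&
      length(.dbl_o_neighbors(mol, i)) == 2L &&
      length(.hydroxyl_neighbors(mol, i)) == 1L &&
      sum(mol$atoms$symbol[mol_neighbors(mol, i)] == "C") == 1L
  }, logical(1)))
}

# sulfonamide sulfur: S(=O)(=O)(N)C
.sulfonamide_s <- function(mol) {
  which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    mol$atoms$symbol[i] == "S" &&
      length(.dbl_o_neighbors(mol, i)) == 2L &&
      sum(mol$atoms$symbol[mol_neighbors(mol, i)] == "N") == 1L &&
      sum(mol$atoms$symbol[mol_neighbors(mol, i)] == "C") == 1L
  }, logical(1)))
}

# all atoms outside `exclude` must be perfluoroalkyl skeleton: C (no H) or F
.remainder_perfluoro <- function(mol, exclude) {
  rest <- setdiff(seq_len(nrow(mol$atoms)), exclude)
  if (length(rest) == 0) return(FALSE)
  all(vapply(rest, function(i) {
    (mol$atoms$symbol[i] == "F") ||
      (mol$atoms$symbol[i] == "C" && mol$atoms$nH[i] == 0L)
  }, logical(1)))
}

# atoms of the branch reachable from `root` without passing through `blocked`
.branch_atoms <- function(mol, root, blocked) {
  seen <- c(blocked, root)
  queue <- root
  out <- root
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in mol_neighbors(mol, v)) {
      if (!(w %in% seen)) {
        seen <- c(seen, w)
        out <- c(out, w)
        queue <- c(queue, w)
      }
    }
  }
  out
}

# saturated CH2 carbon bonded only to carbons/heteroatom ends
.is_ch2 <- function(mol, i) {
  mol$atoms$symbol[i] == "C" && mol$atoms$nH[i] == 2L && mol_is_sp3_carbon(mol, i)
}

# ---- core matchers ---------------------------------------------------------
# Each matcher sees an acyclic aliphatic molecule and returns NULL or
# list(m = alkyl spacer). Whole-molecule accounting (head atoms + perfluoro
# remainder) keeps the patterns mutually exclusive in practice; precedence is
# still fixed by the rule table.

.match_PFCAs <- function(mol) {
  cc <- .carboxyl_carbons(mol)
  if (length(cc) != 1L) return(NULL)
  head <- c(cc, .dbl_o_neighbors(mol, cc), .hydroxyl_neighbors(mol, cc))
  if (.remainder_perfluoro(mol, head)) list(m = 0L) else NULL
}

.match_PFSAs <- function(mol) {
  ss <- .sulfonic_s(mol)
  if (length(ss) != 1L) return(NULL)
  head <- c(ss, .dbl_o_neighbors(mol, ss), .hydroxyl_neighbors(mol, ss))
  if (.remainder_perfluoro(mol, head)) list(m = 0L) else NULL
}

.match_PFPAs <- function(mol) {
  pp <- which(mol$atoms$symbol == "P")
  if (length(pp) != 1L) return(NULL)
  p <- pp[1]
  if (length(.dbl_o_neighbors(mol, p)) != 1L ||
    length(.hydroxyl_neighbors(mol, p)) != 2L ||
    sum(mol$atoms$symbol[mol_neighbors(mol, p)] == "C") != 1L) {
    return(NULL)
  }
  head <- c(p, .dbl_o_neighbors(mol, p), .hydroxyl_neighbors(mol, p))
  if (.remainder_perfluoro(mol, head)) list(m = 0L) else NULL
}

.match_PFPiAs <- function(mol) {
  pp <- which(mol$atoms$symbol == "P")
  if (length(pp) != 1L) return(NULL)
  p <- pp[1]
  if (length(.dbl_o_neighbors(mol, p)) != 1L ||
    length(.hydroxyl_neighbors(mol, p)) != 1L ||
    sum(mol$atoms$symbol[mol_neighbors(mol, p)] == "C") != 2L) {
    return(NULL)
  }
  head <- c(p, .dbl_o_neighbors(mol, p), .hydroxyl_neighbors(mol, p))
  if (.remainder_perfluoro(mol, head)) list(m = 0L) else NULL
}

.match_PFECAs <- function(mol) {
  if (!all(mol$atoms$symbol %in% c("C", "F", "O"))) return(NULL)
  cc <- .carboxyl_carbons(mol)
  if (length(cc) != 1L) return(NULL)
  ethers <- which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    mol$atoms$symbol[i] == "O" && mol$atoms$nH[i] == 0L &&
      length(mol_neighbors(mol, i)) == 2L &&
      all(mol$atoms$symbol[mol_neighbors(mol, i)] == "C")
  }, logical(1)))
  if (length(ethers) == 0) return(NULL)
  head_o <- c(.dbl_o_neighbors(mol, cc), .hydroxyl_neighbors(mol, cc))
  if (!setequal(which(mol$atoms$symbol == "O"), c(head_o, ethers))) return(NULL)
  carbons <- setdiff(which(mol$atoms$symbol == "C"), cc)
  if (all(mol$atoms$nH[carbons] == 0L)) list(m = 0L) else NULL
}

.match_PFESAs <- function(mol) {
  if (!all(mol$atoms$symbol %in% c("C", "F", "O", "S"))) return(NULL)
  ss <- .sulfonic_s(mol)
  if (length(ss) != 1L || sum(mol$atoms$symbol == "S") != 1L) return(NULL)
  ethers <- which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    mol$atoms$symbol[i] == "O" && mol$atoms$nH[i] == 0L &&
      length(mol_neighbors(mol, i)) == 2L &&
      all(mol$atoms$symbol[mol_neighbors(mol, i)] == "C")
  }, logical(1)))
  if (length(ethers) == 0) return(NULL)
  head_o <- c(.dbl_o_neighbors(mol, ss), .hydroxyl_neighbors(mol, ss))
  if (!setequal(which(mol$atoms$symbol == "O"), c(head_o, ethers))) return(NULL)
  carbons <- which(mol$atoms$symbol == "C")
  if (all(mol$atoms$nH[carbons] == 0L)) list(m = 0L) else NULL
}

# FASA family: CnF2n+1-SO2N(CmH2m+1)(arm). The functional arm decides the
# subclass; the saturated N-alkyl length is reported as m.
.fasa_arm_type <- function(mol, root, nidx) {
  atoms <- .branch_atoms(mol, root, nidx)
  syms <- mol$atoms$symbol[atoms]
  n_c <- sum(syms == "C")
  n_o <- sum(syms == "O")
  if (all(syms == "C")) {
    saturated <- all(vapply(atoms, function(i) mol_is_sp3_carbon(mol, i), logical(1)))
    if (saturated) return(list(type = "alkyl", len = n_c))
    return(list(type = "other", len = 0L))
  }
  if (n_c == 2L && n_o == 1L && length(atoms) == 3L) {
    c2 <- setdiff(intersect(mol_neighbors(mol, root), atoms), root)
    c2 <- c2[mol$atoms$symbol[c2] == "C"]
    if (length(c2) == 1L && .is_ch2(mol, root) && .is_ch2(mol, c2) &&
      length(.hydroxyl_neighbors(mol, c2)) == 1L) {
      return(list(type = "hydroxyethyl", len = 2L))
    }
  }
  if (n_c == 2L && n_o == 2L && length(atoms) == 4L) {
    cc <- intersect(.carboxyl_carbons(mol), atoms)
    if (length(cc) == 1L && .is_ch2(mol, root) &&
      cc %in% mol_neighbors(mol, root)) {
      return(list(type = "acetic", len = 1L))
    }
  }
  if (n_o == 2L && n_c %in% c(5L, 6L) && length(atoms) == n_c + 2L) {
    # (meth)acrylate ester at the end of an ethyl spacer
    c2 <- setdiff(intersect(mol_neighbors(mol, root), atoms), root)
    c2 <- c2[mol$atoms$symbol[c2] == "C"]
    if (length(c2) == 1L && .is_ch2(mol, root) && .is_ch2(mol, c2)) {
      eo <- .ether_o_neighbors(mol, c2)
      if (length(eo) == 1L) {
        c3 <- setdiff(mol_neighbors(mol, eo), c2)
        if (length(c3) == 1L && mol$atoms$symbol[c3] == "C" &&
          length(.dbl_o_neighbors(mol, c3)) == 1L) {
          c4 <- setdiff(mol_neighbors(mol, c3), c(eo, .dbl_o_neighbors(mol, c3)))
          if (length(c4) == 1L && mol$atoms$symbol[c4] == "C") {
            dbl_c <- mol_neighbors(mol, c4)[vapply(mol_neighbors(mol, c4), function(k) {
              mol$atoms$symbol[k] == "C" && mol_bond_order(mol, c4, k) == 2L
            }, logical(1))]
            if (length(dbl_c) == 1L && mol$atoms$nH[dbl_c] == 2L) {
              if (n_c == 5L && mol$atoms$nH[c4] == 1L) {
                return(list(type = "acrylate", len = 2L))
              }
              if (n_c == 6L && mol$atoms$nH[c4] == 0L) {
                return(list(type = "methacrylate", len = 2L))
              }
            }
          }
        }
      }
    }
  }
  list(type = "other", len = 0L)
}

.fasa_detect <- function(mol) {
  ss <- .sulfonamide_s(mol)
  if (length(ss) != 1L) return(NULL)
  s <- ss[1]
  nidx <- mol_neighbors(mol, s)[mol$atoms$symbol[mol_neighbors(mol, s)] == "N"]
  arms_roots <- setdiff(mol_neighbors(mol, nidx), s)
  arm_info <- lapply(arms_roots, .fasa_arm_type, mol = mol, nidx = nidx)
  types <- vapply(arm_info, `[[`, character(1), "type")
  if (any(types == "other")) return(NULL)
  functional <- setdiff(types, "alkyl")
  if (length(functional) > 1L) return(NULL)
  head <- c(s, .dbl_o_neighbors(mol, s), nidx,
    unlist(lapply(arms_roots, .branch_atoms, mol = mol, blocked = nidx)))
  if (!.remainder_perfluoro(mol, head)) return(NULL)
  m <- if (any(types == "alkyl")) {
    max(vapply(arm_info[types == "alkyl"], `[[`, integer(1), "len"))
  } else {
    0L
  }
  subclass <- switch(if (length(functional) == 0) "none" else functional,
    none = "FASAs",
    hydroxyethyl = "FASEs",
    acetic = "FASAAs",
    acrylate = "FASACs",
    methacrylate = "FASMACs"
  )
  list(subclass = subclass, m = m)
}

.match_fasa_factory <- function(subclass) {
  force(subclass)
  function(mol) {
    d <- .fasa_detect(mol)
    if (!is.null(d) && d$subclass == subclass) list(m = d$m) else NULL
  }
}

# n:2 fluorotelomer family: CnF2n+1-C2H4-R1 (plus the unsaturated and the
# single-CH2 acid/aldehyde members of the catalog).
.telomer_detect <- function(mol) {
  S <- .perfluoro_set(mol)
  if (length(S) == 0) return(NULL)
  for (ct in S) {
    bridges <- setdiff(mol_neighbors(mol, ct), c(S, which(mol$atoms$symbol == "F")))
    for (c1 in bridges) {
      if (mol$atoms$symbol[c1] != "C") next
      # unsaturated: ct-CF=CH-C(=O)X
      if (mol_f_count(mol, c1) == 1L && mol$atoms$nH[c1] == 0L) {
        v2 <- mol_neighbors(mol, c1)[vapply(mol_neighbors(mol, c1), function(k) {
          mol$atoms$symbol[k] == "C" && mol_bond_order(mol, c1, k) == 2L
        }, logical(1))]
        if (length(v2) == 1L && mol$atoms$nH[v2] == 1L) {
          nxt <- setdiff(mol_neighbors(mol, v2), c1)
          if (length(nxt) == 1L && mol$atoms$symbol[nxt] == "C") {
            fgroup <- mol$atoms$symbol[mol_neighbors(mol, c1)]
            cc <- nxt
            if (cc %in% .carboxyl_carbons(mol)) {
              head <- c(c1, mol_neighbors(mol, c1)[mol$atoms$symbol[mol_neighbors(mol, c1)] == "F"],
                v2, cc, .dbl_o_neighbors(mol, cc), .hydroxyl_neighbors(mol, cc))
              if (.remainder_perfluoro(mol, head)) return(list(subclass = "FTUCAs"))
            }
            if (mol$atoms$nH[cc] == 1L && length(.dbl_o_neighbors(mol, cc)) == 1L) {
              head <- c(c1, mol_neighbors(mol, c1)[mol$atoms$symbol[mol_neighbors(mol, c1)] == "F"],
                v2, cc, .dbl_o_neighbors(mol, cc))
              if (.remainder_perfluoro(mol, head)) return(list(subclass = "FTUALs"))
            }
          }
        }
      }
      # olefin: ct-CH=CH2
      if (mol$atoms$nH[c1] == 1L) {
        v2 <- mol_neighbors(mol, c1)[vapply(mol_neighbors(mol, c1), function(k) {
          mol$atoms$symbol[k] == "C" && mol_bond_order(mol, c1, k) == 2L
        }, logical(1))]
        if (length(v2) == 1L && mol$atoms$nH[v2] == 2L &&
          .remainder_perfluoro(mol, c(c1, v2))) {
          return(list(subclass = "FTOs"))
        }
      }
      if (!.is_ch2(mol, c1)) next
      nxt <- setdiff(mol_neighbors(mol, c1), ct)
      if (length(nxt) != 1L) next
      c2 <- nxt
      if (mol$atoms$symbol[c2] == "C" && c2 %in% .carboxyl_carbons(mol)) {
        head <- c(c1, c2, .dbl_o_neighbors(mol, c2), .hydroxyl_neighbors(mol, c2))
        if (.remainder_perfluoro(mol, head)) return(list(subclass = "FTCAs"))
      }
      if (mol$atoms$symbol[c2] == "C" && mol$atoms$nH[c2] == 1L &&
        length(.dbl_o_neighbors(mol, c2)) == 1L &&
        length(mol_neighbors(mol, c2)) == 2L) {
        head <- c(c1, c2, .dbl_o_neighbors(mol, c2))
        if (.remainder_perfluoro(mol, head)) return(list(subclass = "FTALs"))
      }
      if (!(mol$atoms$symbol[c2] == "C" && .is_ch2(mol, c2))) next
      x <- setdiff(mol_neighbors(mol, c2), c1)
      if (length(x) == 0L) next
      if (length(x) != 1L) next
      xs <- mol$atoms$symbol[x]
      if (xs == "I" && .remainder_perfluoro(mol, c(c1, c2, x))) {
        return(list(subclass = "FTIs"))
      }
      if (xs == "O" && mol$atoms$nH[x] == 1L &&
        .remainder_perfluoro(mol, c(c1, c2, x))) {
        return(list(subclass = "FTOHs"))
      }
      if (xs == "S" && length(.dbl_o_neighbors(mol, x)) == 2L &&
        length(.hydroxyl_neighbors(mol, x)) == 1L) {
        head <- c(c1, c2, x, .dbl_o_neighbors(mol, x), .hydroxyl_neighbors(mol, x))
        if (.remainder_perfluoro(mol, head)) return(list(subclass = "FTSAs"))
      }
      if (xs == "O" && mol$atoms$nH[x] == 0L && length(mol_neighbors(mol, x)) == 2L) {
        y <- setdiff(mol_neighbors(mol, x), c2)
        if (mol$atoms$symbol[y] == "C" && length(.dbl_o_neighbors(mol, y)) == 1L) {
          # telomer (meth)acrylate ester
          c4 <- setdiff(mol_neighbors(mol, y), c(x, .dbl_o_neighbors(mol, y)))
          if (length(c4) == 1L && mol$atoms$symbol[c4] == "C") {
            dbl_c <- mol_neighbors(mol, c4)[vapply(mol_neighbors(mol, c4), function(k) {
              mol$atoms$symbol[k] == "C" && mol_bond_order(mol, c4, k) == 2L
            }, logical(1))]
            if (length(dbl_c) == 1L && mol$atoms$nH[dbl_c] == 2L) {
              extras <- setdiff(mol_neighbors(mol, c4), c(y, dbl_c))
              head <- c(c1, c2, x, y, .dbl_o_neighbors(mol, y), c4, dbl_c, extras)
              if (mol$atoms$nH[c4] == 1L && length(extras) == 0L &&
                .remainder_perfluoro(mol, head)) {
                return(list(subclass = "FTACs"))
              }
              if (mol$atoms$nH[c4] == 0L && length(extras) == 1L &&
                mol$atoms$symbol[extras] == "C" && mol$atoms$nH[extras] == 3L &&
                .remainder_perfluoro(mol, head)) {
                return(list(subclass = "FTMACs"))
              }
            }
          }
        }
        if (mol$atoms$symbol[y] == "P") {
          p <- y
          esters <- .ether_o_neighbors(mol, p)
          ohs <- .hydroxyl_neighbors(mol, p)
          dbl <- .dbl_o_neighbors(mol, p)
          if (length(dbl) == 1L) {
            arm_atoms <- unlist(lapply(esters, function(eo) {
              cc2 <- setdiff(mol_neighbors(mol, eo), p)
              if (length(cc2) == 1L && .is_ch2(mol, cc2)) {
                cc1 <- setdiff(mol_neighbors(mol, cc2), eo)
                if (length(cc1) == 1L && .is_ch2(mol, cc1)) {
                  return(c(eo, cc2, cc1))
                }
              }
              NULL
            }))
            head <- c(p, dbl, ohs, arm_atoms)
            if (length(esters) == 1L && length(ohs) == 2L &&
              length(arm_atoms) == 3L && .remainder_perfluoro(mol, head)) {
              return(list(subclass = "monoPAPs"))
            }
            if (length(esters) == 2L && length(ohs) == 1L &&
              length(arm_atoms) == 6L && .remainder_perfluoro(mol, head)) {
              return(list(subclass = "diPAPs"))
            }
          }
        }
      }
    }
  }
  NULL
}

.match_telomer_factory <- function(subclass) {
  force(subclass)
  function(mol) {
    d <- .telomer_detect(mol)
    if (!is.null(d) && d$subclass == subclass) list(m = 0L) else NULL
  }
}

# perfluoroalkyl PFAA precursors: reactive head directly on the chain
.match_PASFs <- function(mol) {
  ss <- which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    mol$atoms$symbol[i] == "S" &&
      length(.dbl_o_neighbors(mol, i)) == 2L &&
      sum(mol$atoms$symbol[mol_neighbors(mol, i)] %in% c("F", "Cl")) == 1L &&
      sum(mol$atoms$symbol[mol_neighbors(mol, i)] == "C") == 1L
  }, logical(1)))
  if (length(ss) != 1L) return(NULL)
  s <- ss[1]
  hal <- mol_neighbors(mol, s)[mol$atoms$symbol[mol_neighbors(mol, s)] %in% c("F", "Cl")]
  head <- c(s, .dbl_o_neighbors(mol, s), hal)
  if (.remainder_perfluoro(mol, head)) list(m = 0L) else NULL
}

.match_PAFs <- function(mol) {
  cs <- which(vapply(seq_len(nrow(mol$atoms)), function(i) {
    if (!(mol$atoms$symbol[i] == "C" && length(.dbl_o_neighbors(mol, i)) == 1L)) {
      return(FALSE)
    }
    nb <- mol_neighbors(mol, i)
    sum(mol$atoms$symbol[nb] == "F") == 1L && sum(mol$atoms$symbol[nb] == "C") == 1L &&
      length(nb) == 3L
  }, logical(1)))
  if (length(cs) != 1L) return(NULL)
  i <- cs[1]
  f <- mol_neighbors(mol, i)[mol$atoms$symbol[mol_neighbors(mol, i)] == "F"]
  head <- c(i, .dbl_o_neighbors(mol, i), f)
  if (.remainder_perfluoro(mol, head)) list(m = 0L) else NULL
}

.match_PFAIs <- function(mol) {
  ii <- which(mol$atoms$symbol == "I")
  if (length(ii) != 1L) return(NULL)
  nb <- mol_neighbors(mol, ii)
  if (length(nb) != 1L || mol$atoms$symbol[nb] != "C") return(NULL)
  if (.remainder_perfluoro(mol, ii)) list(m = 0L) else NULL
}

# non-PFAA perfluoroalkyls
.match_perfluoroketones <- function(mol) {
  if (!all(mol$atoms$symbol %in% c("C", "F", "O"))) return(NULL)
  os <- which(mol$atoms$symbol == "O")
  if (length(os) == 0) return(NULL)
  ket <- vapply(os, function(o) {
    nb <- mol_neighbors(mol, o)
    length(nb) == 1L && mol_bond_order(mol, o, nb) == 2L &&
      mol$atoms$symbol[nb] == "C" &&
      sum(mol$atoms$symbol[mol_neighbors(mol, nb)] == "C") == 2L
  }, logical(1))
  if (!all(ket)) return(NULL)
  carbons <- which(mol$atoms$symbol == "C")
  if (all(mol$atoms$nH[carbons] == 0L)) list(m = 0L) else NULL
}

.match_perfluoroalcohols <- function(mol) {
  if (!all(mol$atoms$symbol %in% c("C", "F", "O"))) return(NULL)
  os <- which(mol$atoms$symbol == "O")
  if (length(os) == 0) return(NULL)
  oh <- vapply(os, function(o) {
    nb <- mol_neighbors(mol, o)
    length(nb) == 1L && mol_bond_order(mol, o, nb) == 1L &&
      mol$atoms$nH[o] == 1L && mol$atoms$symbol[nb] == "C"
  }, logical(1))
  if (!all(oh)) return(NULL)
  carbons <- which(mol$atoms$symbol == "C")
  if (all(mol$atoms$nH[carbons] == 0L)) list(m = 0L) else NULL
}

.match_perfluoroalkenes <- function(mol) {
  if (!all(mol$atoms$symbol %in% c("C", "F"))) return(NULL)
  if (!any(mol$bonds$order == 2L)) return(NULL)
  carbons <- which(mol$atoms$symbol == "C")
  if (all(mol$atoms$nH[carbons] == 0L)) list(m = 0L) else NULL
}

.match_perfluoroalkanes <- function(mol) {
  if (!all(mol$atoms$symbol %in% c("C", "F"))) return(NULL)
  if (nrow(mol$bonds) > 0 && any(mol$bonds$order != 1L)) return(NULL)
  carbons <- which(mol$atoms$symbol == "C")
  if (all(mol$atoms$nH[carbons] == 0L)) list(m = 0L) else NULL
}

# registry: subclass label -> matcher
.core_matchers <- function() {
  fasa <- c("FASAAs", "FASACs", "FASMACs", "FASEs", "FASAs")
  telo <- c(
    "FTUCAs", "FTUALs", "FTCAs", "FTALs", "FTACs", "FTMACs", "FTSAs",
    "diPAPs", "monoPAPs", "FTIs", "FTOs", "FTOHs"
  )
  out <- list(
    PFCAs = .match_PFCAs, PFSAs = .match_PFSAs, PFPAs = .match_PFPAs,
    PFPiAs = .match_PFPiAs, PFECAs = .match_PFECAs, PFESAs = .match_PFESAs,
    PASFs = .match_PASFs, PAFs = .match_PAFs, PFAIs = .match_PFAIs,
    perfluoroketones = .match_perfluoroketones,
    perfluoroalcohols = .match_perfluoroalcohols,
    perfluoroalkenes = .match_perfluoroalkenes,
    perfluoroalkanes = .match_perfluoroalkanes
  )
  for (s in fasa) out[[s]] <- .match_fasa_factory(s)
  for (s in telo) out[[s]] <- .match_telomer_factory(s)
  out
}

#' The class-subclass rule table
#'
#' Returns the ordered rule table the core module applies: one row per
#' subclass with its class, match order, and a plain-language structural
#' pattern. The table ships as a TSV under `extdata` so the precedence is
#' inspectable and can be updated as the taxonomy evolves; a reordered or
#' subset table can be passed to [pfas_classify()].
#'
#' @param path Optional path to an alternative rule table (TSV with columns
#'   `order`, `subclass`, `class`, `pattern`).
#' @return A tibble with columns `order`, `subclass`, `class`, `pattern`.
#' @export
pfas_ruleset <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pfas_ruleset.tsv", package = "pfasmap")
  }
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tb <- tb[order(tb$order), , drop = FALSE]
  known <- names(.core_matchers())
  bad <- setdiff(tb$subclass, known)
  if (length(bad) > 0) {
    stop("rule table names subclasses with no matcher: ", paste(bad, collapse = ", "))
  }
  tibble::as_tibble(tb)
}

# core module: first matching subclass in rule order wins
.classify_core_mol <- function(mol, ruleset) {
  matchers <- .core_matchers()
  n <- .perfluoro_chain_n(mol)
  for (k in seq_len(nrow(ruleset))) {
    sub <- ruleset$subclass[k]
    hit <- matchers[[sub]](mol)
    if (!is.null(hit)) {
      return(list(
        class = ruleset$class[k], subclass = sub,
        n = n, m = hit$m %||% 0L
      ))
    }
  }
  list(class = "unclassified_aliphatic", subclass = NA_character_, n = n, m = 0L)
}

# full cascade for one canonical SMILES
.classify_one <- function(canonical, ruleset) {
  empty <- tibble::tibble(
    canonical_smiles = canonical, category = NA_character_,
    class = NA_character_, subclass = NA_character_,
    n = NA_integer_, m = NA_integer_,
    ring_opened = NA, rings_opened = NA_integer_
  )
  mol <- mol_from_smiles(canonical)
  if (is.null(mol)) return(empty)

  if (!.module1_pfas(mol)) {
    d <- .derivative_subclass(mol)
    return(tibble::tibble(
      canonical_smiles = canonical,
      category = if (is.na(d)) "not_pfas" else "pfas_derivative",
      class = NA_character_, subclass = d,
      n = 0L, m = 0L, ring_opened = FALSE, rings_opened = 0L
    ))
  }
  if (mol_symbol_count(mol, "Si") > 0) {
    return(tibble::tibble(
      canonical_smiles = canonical, category = "silicon_pfas",
      class = NA_character_, subclass = NA_character_,
      n = .perfluoro_chain_n(mol), m = 0L,
      ring_opened = FALSE, rings_opened = 0L
    ))
  }
  if (any(mol$atoms$aromatic)) {
    return(tibble::tibble(
      canonical_smiles = canonical, category = "side_chain_fluorinated_aromatic",
      class = NA_character_, subclass = NA_character_,
      n = .perfluoro_chain_n(mol), m = 0L,
      ring_opened = FALSE, rings_opened = 0L
    ))
  }
  op <- open_rings_mol(mol)
  core <- .classify_core_mol(op$mol, attr(ruleset, "tbl") %||% ruleset)
  tibble::tibble(
    canonical_smiles = canonical, category = "aliphatic_pfas",
    class = core$class, subclass = core$subclass,
    n = core$n, m = core$m,
    ring_opened = op$rings_opened > 0L, rings_opened = op$rings_opened
  )
}

#' Classify structures into the PFAS class/subclass hierarchy
#'
#' Applies the full rule cascade: (1) the PFAS definition filter (at least
#' one fully fluorinated -CF3 or chain -CF2- carbon), with near-misses
#' subclassed as PFAS derivatives; (2) the silicon filter; (3) the side-chain
#' fluorinated aromatic filter; (4) carbocycle ring opening; and the core
#' Buck/OECD class-subclass rules. Every parseable structure receives exactly
#' one result.
#'
#' @param data A data frame with a `canonical_smiles` column (typically from
#'   [pfas_standardize()] / [pfas_deduplicate()]), or a character vector of
#'   SMILES, which are standardized first.
#' @param ruleset Rule table from [pfas_ruleset()]; controls core-module
#'   precedence.
#' @return A tibble with one row per structure: `canonical_smiles`,
#'   `category` (one of not_pfas, pfas_derivative, silicon_pfas,
#'   side_chain_fluorinated_aromatic, aliphatic_pfas), `class`, `subclass`,
#'   the perfluoroalkyl chain length `n`, the N-alkyl spacer `m`,
#'   `ring_opened`, and `rings_opened`. Identifier columns present in `data`
#'   are carried through.
#' @examples
#' pfas_classify(c("CCO", "OC(=O)C(F)(F)C(F)(F)C(F)(F)F"))
#' @export
pfas_classify <- function(data, ruleset = pfas_ruleset()) {
  if (is.character(data)) {
    std <- pfas_standardize(data)
    data <- std[std$valid, c("id", "canonical_smiles")]
  }
  stopifnot("canonical_smiles" %in% names(data))
  res <- dplyr::bind_rows(
    purrr::map(data$canonical_smiles, .classify_one, ruleset = ruleset)
  )
  extra <- setdiff(names(data), names(res))
  if (length(extra) > 0) {
    res <- dplyr::bind_cols(data[, extra, drop = FALSE], res)
  }
  res
}

#' Definition filter: does a structure contain a fully fluorinated carbon?
#'
#' @param smiles Character vector of SMILES (standardized internally).
#' @return Logical vector: `TRUE` when the structure carries at least one
#'   terminal -CF3 or chain -CF2- group.
#' @export
contains_perfluorinated_carbon <- function(smiles) {
  vapply(canonicalize_smiles(smiles), function(s) {
    if (is.na(s)) return(NA)
    mol <- mol_from_smiles(s)
    if (is.null(mol)) return(NA)
    .module1_pfas(mol)
  }, logical(1), USE.NAMES = FALSE)
}

#' Subclassify structures that miss the PFAS definition
#'
#' For structures without a fully fluorinated carbon, tests the three
#' derivative patterns in order: fluorine substituted by Cl/Br on an
#' otherwise perfluorinated carbon, a fluorinated C=C or C=O carbon, and a
#' fluorinated aromatic carbon.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector: the derivative subclass, or `"not_pfas"`; `NA`
#'   when the structure passes the definition filter (the derivative rules do
#'   not apply).
#' @export
classify_derivative <- function(smiles) {
  vapply(canonicalize_smiles(smiles), function(s) {
    if (is.na(s)) return(NA_character_)
    mol <- mol_from_smiles(s)
    if (is.null(mol)) return(NA_character_)
    if (.module1_pfas(mol)) return(NA_character_)
    d <- .derivative_subclass(mol)
    if (is.na(d)) "not_pfas" else d
  }, character(1), USE.NAMES = FALSE)
}

#' Silicon filter
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector: `TRUE` when the structure contains silicon.
#' @export
contains_silicon <- function(smiles) {
  vapply(canonicalize_smiles(smiles), function(s) {
    if (is.na(s)) return(NA)
    mol <- mol_from_smiles(s)
    if (is.null(mol)) return(NA)
    mol_symbol_count(mol, "Si") > 0
  }, logical(1), USE.NAMES = FALSE)
}

#' Side-chain fluorinated aromatic filter
#'
#' A structure that passes the definition filter and carries an aromatic ring
#' is a side-chain fluorinated aromatic: its fully fluorinated carbons are
#' necessarily aliphatic, so the perfluorinated content sits on a side chain.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector.
#' @export
is_side_chain_fluorinated_aromatic <- function(smiles) {
  vapply(canonicalize_smiles(smiles), function(s) {
    if (is.na(s)) return(NA)
    mol <- mol_from_smiles(s)
    if (is.null(mol)) return(NA)
    .module1_pfas(mol) && any(mol$atoms$aromatic)
  }, logical(1), USE.NAMES = FALSE)
}

#' Core class-subclass assignment for acyclic aliphatic PFAS
#'
#' Applies only the core module (no filters, no ring opening): the first
#' matching subclass in the rule-table order wins.
#'
#' @param smiles Character vector of SMILES of acyclic aliphatic PFAS.
#' @param ruleset Rule table from [pfas_ruleset()].
#' @return A tibble with `canonical_smiles`, `class`, `subclass`, `n`, `m`.
#' @export
classify_core <- function(smiles, ruleset = pfas_ruleset()) {
  dplyr::bind_rows(purrr::map(canonicalize_smiles(smiles), function(s) {
    mol <- if (is.na(s)) NULL else mol_from_smiles(s)
    if (is.null(mol)) {
      return(tibble::tibble(
        canonical_smiles = s, class = NA_character_,
        subclass = NA_character_, n = NA_integer_, m = NA_integer_
      ))
    }
    core <- .classify_core_mol(mol, ruleset)
    tibble::tibble(
      canonical_smiles = s, class = core$class, subclass = core$subclass,
      n = core$n, m = core$m
    )
  }))
}
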