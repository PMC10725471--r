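# Dimer-interface pharmacophore modelling and conformer-library screening.
#
# A pharmacophore model is a set of typed 3D feature points derived from
# named residues of a structure. A ligand conformer matches when an
# injective, type-compatible correspondence of at least `min_matched`
# features exists whose rigid superposition leaves every paired distance
# within the tolerance and whose matched types satisfy the composition rule.

.feature_kinds <- c("hydrophobic", "aromatic", "positive", "negative",
                    "donor", "acceptor")
.polar_kinds <- c("donor", "acceptor", "positive", "negative")

#' Composition rule for pharmacophore matches
#'
#' Encodes the screening requirement that a hit satisfies 4-5 feature
#' points built from three hydrophobic groups, one aromatic group and one
#' hydrogen-bonding or charged group. Because the published rule leaves the
#' composition of a 4-point match ambiguous, the polar/charged requirement
#' is split by match size: `required_polar_4` applies to 4-point matches
#' (default 0) and `required_polar_5` to matches of 5 or more points
#' (default 1).
#'
#' @param min_matched Minimum number of matched features (>= 4).
#' @param required_hydrophobic Minimum hydrophobic features in a match.
#' @param required_aromatic Minimum aromatic features in a match.
#' @param required_polar_4,required_polar_5 Minimum donor/acceptor/
#'   positive/negative features for 4-point and >= 5-point matches.
#' @return Object of class `"composition_rule"`.
#' @export
composition_rule <- function(min_matched = 4L, required_hydrophobic = 3L,
                             required_aromatic = 1L, required_polar_4 = 0L,
                             required_polar_5 = 1L) {
  if (min_matched < 4L) stop("min_matched must be at least 4")
  structure(
    list(min_matched = as.integer(min_matched),
         required_hydrophobic = as.integer(required_hydrophobic),
         required_aromatic = as.integer(required_aromatic),
         required_polar_4 = as.integer(required_polar_4),
         required_polar_5 = as.integer(required_polar_5)),
    class = "composition_rule"
  )
}

rule_satisfied <- function(rule, kinds) {
  n <- length(kinds)
  if (n < rule$min_matched) return(FALSE)
  req_polar <- if (n >= 5L) rule$required_polar_5 else rule$required_polar_4
  sum(kinds == "hydrophobic") >= rule$required_hydrophobic &&
    sum(kinds == "aromatic") >= rule$required_aromatic &&
    sum(kinds %in% .polar_kinds) >= req_polar
}

#' Default feature specification for the BAX dimer-interface model
#'
#' Nine features from the residues lining the trigger-site/C-terminal
#' interface of the autoinhibited dimer: hydrophobic points at the
#' sidechain heavy-atom centroids of Q28, L45, L47 and T172; an aromatic
#' point at the F176 ring centroid; a positive point at the R109
#' guanidinium centroid (NH1/NH2/CZ); a negative point at the D48
#' carboxylate centroid (OD1/OD2/CG); a donor at the A46 backbone amide
#' nitrogen; and an acceptor at the Y164 hydroxyl oxygen. Every placement
#' is overridable by editing the returned data.frame.
#'
#' @return data.frame with columns `residue_number`, `kind`, `atoms`
#'   (list-column of atom-name vectors or `"sidechain"`).
#' @export
bax_interface_features <- function() {
  spec <- data.frame(
    residue_number = c(28L, 45L, 47L, 172L, 176L, 109L, 48L, 46L, 164L),
    kind = c("hydrophobic", "hydrophobic", "hydrophobic", "hydrophobic",
             "aromatic", "positive", "negative", "donor", "acceptor"),
    stringsAsFactors = FALSE
  )
  spec$atoms <- list(
    "sidechain", "sidechain", "sidechain", "sidechain",
    c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    c("NH1", "NH2", "CZ"),
    c("OD1", "OD2", "CG"),
    "N",
    "OH"
  )
  spec
}

#' Build a pharmacophore model from a structure
#'
#' Places one feature point per specification row at the centroid of the
#' resolved atom set.
#'
#' @param structure A `"bax_structure"` (e.g. the dimer-interface
#'   structure).
#' @param feature_spec data.frame as returned by
#'   [bax_interface_features()].
#' @param tolerance Matching radius in Angstrom (default 2).
#' @param rule A [composition_rule()].
#' @param chain_id,model Passed to [select_atoms()].
#' @return Object of class `"pharmacophore_model"`: list with `features`
#'   (data.frame `kind`, `x`, `y`, `z`, `source_tag`), `tolerance`, `rule`.
#' @export
build_pharmacophore <- function(structure,
                                feature_spec = bax_interface_features(),
                                tolerance = 2.0,
                                rule = composition_rule(),
                                chain_id = NULL, model = 1L) {
  if (nrow(feature_spec) == 0L) stop("empty feature specification")
  bad <- !feature_spec$kind %in% .feature_kinds
  if (any(bad)) stop("unknown feature kind: ",
                     paste(unique(feature_spec$kind[bad]), collapse = ", "))
  pos <- t(vapply(seq_len(nrow(feature_spec)), function(i) {
    xyz <- select_atoms(structure, feature_spec$residue_number[i],
                        atom = feature_spec$atoms[[i]],
                        chain_id = chain_id, model = model)
    colMeans(xyz)
  }, numeric(3)))
  features <- data.frame(
    kind = feature_spec$kind,
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    source_tag = paste0(feature_spec$kind, "_",
                        feature_spec$residue_number),
    stringsAsFactors = FALSE
  )
  new_pharmacophore(features, tolerance, rule)
}

new_pharmacophore <- function(features, tolerance, rule) {
  if (any(!is.finite(as.matrix(features[, c("x", "y", "z")])))) {
    stop("non-finite feature position")
  }
  structure(list(features = features, tolerance = tolerance, rule = rule),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("<pharmacophore_model> ", nrow(x$features), " features (",
      paste(names(table(x$features$kind)), table(x$features$kind),
            sep = ":", collapse = " "),
      "), tolerance ", x$tolerance, " A\n", sep = "")
  invisible(x)
}

#' Create a ligand conformer
#'
#' @param id Ligand identifier.
#' @param features data.frame with columns `kind`, `x`, `y`, `z` (feature
#'   positions in any rigid ligand-local frame, Angstrom).
#' @return Object of class `"ligand_conformer"`.
#' @export
ligand_conformer <- function(id, features) {
  if (nrow(features) < 1L) stop("conformer needs at least one feature")
  bad <- !features$kind %in% .feature_kinds
  if (any(bad)) stop("unknown feature kind: ",
                     paste(unique(features$kind[bad]), collapse = ", "))
  structure(list(id = as.character(id),
                 features = as.data.frame(features)),
            class = "ligand_conformer")
}

feature_matrix <- function(features) {
  as.matrix(features[, c("x", "y", "z")])
}

kind_compatible <- function(model_kind, ligand_kind,
                            aromatic_as_hydrophobic = FALSE) {
  model_kind == ligand_kind |
    (aromatic_as_hydrophobic &
       model_kind == "hydrophobic" & ligand_kind == "aromatic")
}

#' Enumerate candidate feature correspondences
#'
#' Depth-first enumeration of all injective, kind-compatible mappings of
#' size at least `min_size` between model and conformer features, pruned by
#' pairwise distance consistency: a partial mapping is extended only while
#' `|d_model(i,j) - d_ligand(a,b)| <= 2 * tolerance` holds for every mapped
#' pair. The bound is sound: a mapping whose superposition leaves every
#' paired distance within `tolerance` can change any pairwise distance by
#' at most `2 * tolerance`, so no oracle-accepted mapping is pruned. Each
#' mapping is returned exactly once.
#'
#' @param model A `"pharmacophore_model"`.
#' @param conformer A `"ligand_conformer"`.
#' @param tolerance Matching radius (Angstrom); defaults to the model's.
#' @param min_size Minimum mapping size; defaults to the rule's
#'   `min_matched`.
#' @param aromatic_as_hydrophobic Allow ligand aromatic features to match
#'   hydrophobic model features (default `FALSE`).
#' @return List of two-column integer matrices (`model`, `ligand`), rows
#'   sorted by model feature index.
#' @export
enumerate_correspondences <- function(model, conformer,
                                      tolerance = model$tolerance,
                                      min_size = model$rule$min_matched,
                                      aromatic_as_hydrophobic = FALSE) {
  if (tolerance <= 0) stop("tolerance must be positive")
  mk <- model$features$kind
  lk <- conformer$features$kind
  Pm <- feature_matrix(model$features)
  Pl <- feature_matrix(conformer$features)
  dm <- as.matrix(stats::dist(Pm))
  dl <- as.matrix(stats::dist(Pl))
  nm <- nrow(Pm); nl <- nrow(Pl)
  cand <- lapply(seq_len(nm), function(i) {
    which(kind_compatible(mk[i], lk, aromatic_as_hydrophobic))
  })
  results <- list()
  nres <- 0L
  # assigned: model indices, lig: matched ligand indices (parallel)
  recurse <- function(i, mods, ligs) {
    if (length(mods) >= min_size) {
      nres <<- nres + 1L
      results[[nres]] <<- cbind(model = mods, ligand = ligs)
    }
    if (i > nm) return()
    # upper bound on achievable size
    if (length(mods) + (nm - i + 1L) < min_size) return()
    for (j in seq(i, nm)) {
      for (a in cand[[j]]) {
        if (a %in% ligs) next
        ok <- TRUE
        for (t in seq_along(mods)) {
          if (abs(dm[mods[t], j] - dl[ligs[t], a]) > 2 * tolerance) {
            ok <- FALSE; break
          }
        }
        if (ok) recurse(j + 1L, c(mods, j), c(ligs, a))
      }
    }
  }
  recurse(1L, integer(0), integer(0))
  results
}

#' Match a ligand conformer against a pharmacophore model
#'
#' Every candidate correspondence from [enumerate_correspondences()] is
#' rigidly superposed ([kabsch_superpose()]) onto the model features; a
#' mapping is valid when all post-alignment paired distances are within the
#' tolerance and the matched feature types satisfy the composition rule.
#' Among valid mappings the winner maximizes
#' `fit_score = n_matched - alignment_rmsd / tolerance`, ties broken by
#' lower RMSD then by lexicographically smallest mapping, which makes the
#' result deterministic. The fit score is a package-defined ranking
#' statistic and is not comparable to proprietary screening scores.
#'
#' @inheritParams enumerate_correspondences
#' @param rule A [composition_rule()]; defaults to the model's.
#' @return Object of class `"match_result"`: list with `ligand_id`,
#'   `passed`, `n_matched`, `alignment_rmsd`, `fit_score`, `matched_pairs`.
#' @export
match_conformer <- function(model, conformer,
                            tolerance = model$tolerance,
                            rule = model$rule,
                            aromatic_as_hydrophobic = FALSE) {
  maps <- enumerate_correspondences(model, conformer, tolerance,
                                    min_size = rule$min_matched,
                                    aromatic_as_hydrophobic =
                                      aromatic_as_hydrophobic)
  Pm <- feature_matrix(model$features)
  Pl <- feature_matrix(conformer$features)
  mk <- model$features$kind
  best <- NULL
  for (mp in maps) {
    if (!rule_satisfied(rule, mk[mp[, 1L]])) next
    fit <- kabsch_superpose(Pm[mp[, 1L], , drop = FALSE],
                            Pl[mp[, 2L], , drop = FALSE])
    aligned <- fit$transform(Pl[mp[, 2L], , drop = FALSE])
    pd <- sqrt(rowSums((aligned - Pm[mp[, 1L], , drop = FALSE])^2))
    if (any(pd > tolerance)) next
    score <- nrow(mp) - fit$rmsd / tolerance
    cand <- list(mp = mp, rmsd = fit$rmsd, score = score)
    if (is.null(best) ||
        score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 && fit$rmsd < best$rmsd - 1e-12) ||
        (abs(score - best$score) <= 1e-12 &&
         abs(fit$rmsd - best$rmsd) <= 1e-12 &&
         .map_less(mp, best$mp))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    res <- list(ligand_id = conformer$id, passed = FALSE, n_matched = 0L,
                alignment_rmsd = NA_real_, fit_score = -Inf,
                matched_pairs = NULL)
  } else {
    res <- list(ligand_id = conformer$id, passed = TRUE,
                n_matched = nrow(best$mp), alignment_rmsd = best$rmsd,
                fit_score = best$score, matched_pairs = best$mp)
  }
  class(res) <- "match_result"
  res
}

# lexicographic order on the flattened (model, ligand) index sequence
.map_less <- function(a, b) {
  va <- as.vector(t(a)); vb <- as.vector(t(b))
  n <- min(length(va), length(vb))
  for (i in seq_len(n)) {
    if (va[i] < vb[i]) return(TRUE)
    if (va[i] > vb[i]) return(FALSE)
  }
  length(va) < length(vb)
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", x$ligand_id, ": ",
      if (x$passed) paste0("PASS n=", x$n_matched, " rmsd=",
                           signif(x$alignment_rmsd, 4), " score=",
                           signif(x$fit_score, 4))
      else "no valid mapping", "\n", sep = "")
  invisible(x)
}

#' Screen a conformer library against a pharmacophore model
#'
#' Matches every conformer and ranks by (`passed` desc, `fit_score` desc,
#' `ligand_id` asc); at most `top_k` rows are returned.
#'
#' @inheritParams match_conformer
#' @param conformers List of `"ligand_conformer"` objects.
#' @param top_k Maximum number of ranked rows (>= 1).
#' @return data.frame with columns `rank`, `ligand_id`, `passed`,
#'   `n_matched`, `alignment_rmsd`, `fit_score`.
#' @export
screen_library <- function(model, conformers, tolerance = model$tolerance,
                           rule = model$rule, top_k = 1000L,
                           aromatic_as_hydrophobic = FALSE) {
  if (top_k < 1L) stop("top_k must be at least 1")
  if (length(conformers) == 0L) {
    return(data.frame(rank = integer(0), ligand_id = character(0),
                      passed = logical(0), n_matched = integer(0),
                      alignment_rmsd = numeric(0), fit_score = numeric(0)))
  }
  rows <- lapply(conformers, function(cf) {
    r <- match_conformer(model, cf, tolerance, rule,
                         aromatic_as_hydrophobic)
    data.frame(ligand_id = r$ligand_id, passed = r$passed,
               n_matched = r$n_matched,
               alignment_rmsd = r$alignment_rmsd,
               fit_score = r$fit_score, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$passed, -tab$fit_score, tab$ligand_id)
  tab <- tab[ord, , drop = FALSE]
  tab <- utils::head(tab, top_k)
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Read/write a conformer library as TSV
#'
#' The TSV has columns `ligand_id`, `feature_kind`, `x`, `y`, `z`
#' (Angstrom), one row per feature.
#'
#' @param file Path to the TSV file.
#' @return For the reader, a list of `"ligand_conformer"` objects.
#' @export
read_conformer_library <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("ligand_id", "feature_kind", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("conformer TSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(tab, tab$ligand_id)[unique(tab$ligand_id)], function(d) {
    ligand_conformer(d$ligand_id[1L],
                     data.frame(kind = d$feature_kind,
                                x = d$x, y = d$y, z = d$z,
                                stringsAsFactors = FALSE))
  })
}

#' @param conformers List of `"ligand_conformer"` objects.
#' @rdname read_conformer_library
#' @export
write_conformer_library <- function(conformers, file) {
  tab <- do.call(rbind, lapply(conformers, function(cf) {
    data.frame(ligand_id = cf$id, feature_kind = cf$features$kind,
               x = cf$features$x, y = cf$features$y, z = cf$features$z,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Serialize a pharmacophore model to YAML
#'
#' @param model A `"pharmacophore_model"`.
#' @param file Path to write (for [read_pharmacophore()], to read).
#' @export
write_pharmacophore <- function(model, file) {
  obj <- list(
    tolerance = model$tolerance,
    rule = unclass(model$rule),
    features = lapply(seq_len(nrow(model$features)), function(i) {
      f <- model$features[i, ]
      list(kind = f$kind, position = c(f$x, f$y, f$z),
           source_tag = f$source_tag)
    })
  )
  yaml::write_yaml(obj, file, precision = 15L)
  invisible(file)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(file) {
  obj <- yaml::read_yaml(file)
  pos <- t(vapply(obj$features, function(f) as.numeric(f$position),
                  numeric(3)))
  features <- data.frame(
    kind = vapply(obj$features, `[[`, character(1), "kind"),
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    source_tag = vapply(obj$features, function(f)
      as.character(f$source_tag %||% ""), character(1)),
    stringsAsFactors = FALSE
  )
  rule <- do.call(composition_rule, obj$rule)
  new_pharmacophore(features, obj$tolerance, rule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
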