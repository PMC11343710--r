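# The discrete model space: candidate pedigrees linking two focal
# individuals, with implied kinship coefficients and matrilineal
# connectivity. The catalogue itself is data (inst/extdata), not code.

#' Enumerate the candidate pedigrees linking two focal individuals
#'
#' Loads the catalogue of 11 topologies consistent with first- or
#' second-degree autosomal relatedness — uncle, maternal grandfather, double
#' first cousins, paternal grandfather, maternal half-siblings, father, full
#' siblings, and the four reversed-direction variants — substitutes the
#' focal ids for the placeholders, and computes each model's kinship
#' coefficients, degree and matrilineal connectivity.
#'
#' @param focalA,focalB ids of the two focal individuals (A is the candidate
#'   senior/earlier individual in models 1-7).
#' @param catalogue_path optional path to an alternative catalogue JSON.
#' @return list of `pedigree_model` objects, one per catalogued topology.
#' @export
enumerate_candidate_pedigrees <- function(focalA = "A", focalB = "B",
                                          catalogue_path = NULL) {
  if (is.null(catalogue_path)) {
    catalogue_path <- system.file("extdata", "pedigree_catalogue.json",
                                  package = "dynastikin")
  }
  dk_assert(nzchar(catalogue_path) && file.exists(catalogue_path),
            "pedigree catalogue not found", "dk_input_error")
  cat_raw <- jsonlite::read_json(catalogue_path)
  lapply(cat_raw$models, function(m) pedigree_model_from_record(m, focalA, focalB))
}

# build a pedigree_model from one catalogue record, substituting focal ids
pedigree_model_from_record <- function(rec, focalA, focalB) {
  subst <- function(x) {
    x[x == "A"] <- focalA
    x[x == "B"] <- focalB
    x
  }
  nodes <- data.frame(
    id = subst(vapply(rec$nodes, `[[`, "", "id")),
    sex = vapply(rec$nodes, `[[`, "", "sex"),
    observed = vapply(rec$nodes, function(n) isTRUE(n$observed), NA),
    stringsAsFactors = FALSE)
  links <- data.frame(
    child = subst(vapply(rec$links, `[[`, "", "child")),
    parent = subst(vapply(rec$links, `[[`, "", "parent")),
    type = vapply(rec$links, `[[`, "", "type"),
    stringsAsFactors = FALSE)
  chain <- data.frame(
    node = subst(vapply(rec$chain, `[[`, "", "node")),
    parent = subst(vapply(rec$chain, function(s)
      if (is.null(s$parent)) NA_character_ else s$parent, "")),
    link = vapply(rec$chain, function(s)
      if (is.null(s$link)) NA_character_ else s$link, ""),
    stringsAsFactors = FALSE)
  label <- sub("\\bA\\b", focalA, rec$label)
  label <- sub("\\bB\\b", focalB, label)
  model <- structure(
    list(model_id = rec$model_id, label = label,
         focalA = focalA, focalB = focalB,
         nodes = nodes, links = links, chain = chain),
    class = "pedigree_model")
  validate_pedigree_model(model)
  k <- kinship_coefficients(model)
  model$k0 <- k[["k0"]]; model$k1 <- k[["k1"]]; model$k2 <- k[["k2"]]
  model$r <- k[["r"]]
  model$degree <- if (abs(model$r - 1/2) < 1e-12) 1L
  else if (abs(model$r - 1/4) < 1e-12) 2L
  else dk_error(sprintf("model %d: r = %g is neither first nor second degree",
                        rec$model_id, model$r), "dk_validation_error")
  mp <- matrilineal_path(model)
  model$matrilineal_connected <- mp$connected
  model$matrilineal_nodes <- mp$path
  model
}

validate_pedigree_model <- function(model) {
  with(model, {
    dk_assert(!anyDuplicated(nodes$id), "duplicate node ids")
    dk_assert(all(links$child %in% nodes$id) && all(links$parent %in% nodes$id),
              "link endpoints must be catalogued nodes")
    for (ty in c("mother", "father")) {
      tab <- table(links$child[links$type == ty])
      dk_assert(all(tab <= 1), sprintf("a node with two %ss", ty))
    }
    sex_of <- stats::setNames(nodes$sex, nodes$id)
    dk_assert(all(sex_of[links$parent[links$type == "mother"]] == "XX"),
              "mothers must be XX")
    dk_assert(all(sex_of[links$parent[links$type == "father"]] == "XY"),
              "fathers must be XY")
    # acyclic iff repeatedly stripping parentless nodes empties the graph
    remaining <- nodes$id
    lk <- links
    repeat {
      founders <- setdiff(remaining, lk$child)
      if (length(founders) == 0) break
      remaining <- setdiff(remaining, founders)
      lk <- lk[lk$parent %in% remaining, , drop = FALSE]
      if (length(remaining) == 0) break
    }
    dk_assert(length(remaining) == 0, "pedigree contains a directed cycle")
  })
  invisible(model)
}

#' @export
print.pedigree_model <- function(x, ...) {
  cat(sprintf("<pedigree_model %d> %s\n  degree %d (k0=%.4g, k1=%.4g, k2=%.4g, r=%.4g)%s\n",
              x$model_id, x$label, x$degree, x$k0, x$k1, x$k2, x$r,
              if (x$matrilineal_connected) "  [matrilineal]" else ""))
  invisible(x)
}

# parents of a node as named character (mother, father), NA when absent
node_parents <- function(model, id) {
  l <- model$links[model$links$child == id, , drop = FALSE]
  c(mother = if ("mother" %in% l$type) l$parent[l$type == "mother"] else NA_character_,
    father = if ("father" %in% l$type) l$parent[l$type == "father"] else NA_character_)
}

# node depth: 0 for founders, 1 + max parent depth otherwise
node_depths <- function(model) {
  depth <- stats::setNames(rep(NA_real_, nrow(model$nodes)), model$nodes$id)
  get_depth <- function(id) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    p <- node_parents(model, id)
    p <- p[!is.na(p)]
    d <- if (length(p) == 0) 0 else 1 + max(vapply(p, get_depth, 0))
    depth[[id]] <<- d
    d
  }
  for (id in model$nodes$id) get_depth(id)
  depth
}

#' Kinship coefficients implied by a pedigree model
#'
#' Exact coefficients for the focal pair under the topology, from the
#' standard recursive kinship algorithm: the kinship coefficient phi is
#' computed over all catalogued parent links (founders unrelated and
#' non-inbred), then `r = 2 phi(A, B)`,
#' `k2 = phi(mA,mB) phi(fA,fB) + phi(mA,fB) phi(fA,mB)` (zero if either
#' focal individual is a founder), `k1 = 4 phi - 2 k2`, `k0 = 1 - k1 - k2`.
#'
#' @param model a `pedigree_model`.
#' @return named numeric vector `(k0, k1, k2, r)`.
#' @export
kinship_coefficients <- function(model) {
  depth <- node_depths(model)
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      p <- node_parents(model, x)
      f <- if (any(is.na(p))) 0 else phi(p[["mother"]], p[["father"]])
      0.5 * (1 + f)
    } else {
      # recurse on the deeper node (never an ancestor of the shallower one);
      # a missing parent is an unrelated anonymous founder, contributing 0
      if (depth[[x]] < depth[[y]]) { tmp <- x; x <- y; y <- tmp }
      p <- node_parents(model, x)
      0.5 * ((if (is.na(p[["mother"]])) 0 else phi(p[["mother"]], y)) +
             (if (is.na(p[["father"]])) 0 else phi(p[["father"]], y)))
    }
    memo[[key]] <- val
    val
  }
  A <- model$focalA; B <- model$focalB
  pA <- node_parents(model, A); pB <- node_parents(model, B)
  if (A == B) dk_error("focal pair must be two individuals", "dk_input_error")
  phiAB <- phi(A, B)
  if (phiAB == 0) dk_error("focal pair disconnected under this topology",
                           "dk_no_relationship_error")
  k2 <- if (any(is.na(pA)) || any(is.na(pB))) 0 else
    phi(pA[["mother"]], pB[["mother"]]) * phi(pA[["father"]], pB[["father"]]) +
    phi(pA[["mother"]], pB[["father"]]) * phi(pA[["father"]], pB[["mother"]])
  r <- 2 * phiAB
  k1 <- 4 * phiAB - 2 * k2
  k0 <- 1 - k1 - k2
  c(k0 = k0, k1 = k1, k2 = k2, r = r)
}

#' Matrilineal connectivity of the focal pair
#'
#' The focal pair is matrilineally connected when both trace, through
#' unbroken mother links inside the pedigree, to a shared matriline —
#' exactly the condition for an obligate mitochondrial haplotype match.
#'
#' @param model a `pedigree_model`.
#' @return list with `connected` (flag) and `path` (the matriline node ids
#'   of both focal individuals, for reporting).
#' @export
matrilineal_path <- function(model) {
  matriline <- function(id) {
    out <- id
    repeat {
      m <- node_parents(model, id)[["mother"]]
      if (is.na(m)) break
      out <- c(out, m)
      id <- m
    }
    out
  }
  la <- matriline(model$focalA)
  lb <- matriline(model$focalB)
  shared <- intersect(la, lb)
  list(connected = length(shared) > 0,
       path = list(A = la, B = lb, shared = shared))
}

#' Human-readable catalogue summary
#'
#' @param models output of [enumerate_candidate_pedigrees()].
#' @return a data frame, one row per model, printed by the `pedigree list`
#'   CLI subcommand.
#' @export
pedigree_catalogue_summary <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(model_id = m$model_id, label = m$label, degree = m$degree,
               k0 = m$k0, k1 = m$k1, k2 = m$k2, r = m$r,
               matrilineal = m$matrilineal_connected,
               stringsAsFactors = FALSE)
  }))
}
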