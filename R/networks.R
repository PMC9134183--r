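#' Define a reaction within a flow-reactor topology
#'
#' Binds the slots of a registered rate law to species of a network. Substrate
#' slots are consumed (stoichiometry -1), `products` are produced (+1), and
#' modifier slots (inhibitors, products acting as inhibitors) enter the rate
#' but are not consumed by it.
#'
#' @param law Rate-law registry key (see [list_rate_laws()]).
#' @param substrates Named character vector mapping the law's substrate slots
#'   to species names, e.g. `c(A = "Glc", B = "NAD")`.
#' @param products Character vector of species produced 1:1.
#' @param modifiers Named character vector mapping modifier slots to species.
#' @param enzyme Enzyme label; parameters of this reaction are named
#'   `<enzyme>_<role>` by default, and the effective enzyme loading is taken
#'   from the `enz_<enzyme>` condition column.
#' @return A `kinflow_reaction` list.
#' @examples
#' reaction("bi_mm", substrates = c(A = "Glc", B = "NAD"),
#'          products = c("GDL", "NADH"), enzyme = "GDH")
#' @export
reaction <- function(law, substrates, products, modifiers = character(),
                     enzyme = "E") {
  lw <- rate_law(law)
  if (!setequal(names(substrates), lw$substrates) ||
      length(substrates) != length(lw$substrates)) {
    abort(sprintf("law '%s' needs substrate slots: %s",
                  law, paste(lw$substrates, collapse = ", ")))
  }
  mod_names <- if (is.null(names(modifiers))) character() else names(modifiers)
  if (!setequal(mod_names, lw$modifiers) ||
      length(modifiers) != length(lw$modifiers)) {
    abort(sprintf("law '%s' needs modifier slots: %s",
                  law, paste(lw$modifiers, collapse = ", ")))
  }
  substrates <- substrates[lw$substrates]
  if (length(modifiers)) modifiers <- modifiers[lw$modifiers]
  roles <- lw$roles
  for (slot in names(substrates)) {
    roles <- gsub(paste0("{", slot, "}"), substrates[[slot]], roles, fixed = TRUE)
  }
  structure(
    list(law = law, substrates = unname(substrates),
         products = unname(products), modifiers = unname(modifiers),
         enzyme = enzyme, roles = roles),
    class = "kinflow_reaction"
  )
}

#' Define a flow-reactor network topology
#'
#' A topology is a set of species, reactions catalyzed by bead-immobilized
#' enzymes, and the subset of species a detector reports. The reactor model
#' adds first-order in/outflow at flow constant `k_f` to every species.
#'
#' @param id Topology identifier used in observation tables.
#' @param species Ordered character vector of species names.
#' @param reactions List of [reaction()] objects.
#' @param observables Species reported by the detector (subset of `species`).
#' @return A `kinflow_network` with a species-by-reaction stoichiometry matrix.
#' @export
flow_network <- function(id, species, reactions, observables = species) {
  stopifnot(is.character(species), length(species) > 0)
  if (!all(observables %in% species)) {
    abort("`observables` must be a subset of `species`.")
  }
  n_s <- length(species)
  stoich <- matrix(0L, n_s, length(reactions),
                   dimnames = list(species, NULL))
  for (r in seq_along(reactions)) {
    rx <- reactions[[r]]
    if (!inherits(rx, "kinflow_reaction")) abort("reactions must be built with reaction().")
    touched <- c(rx$substrates, rx$products, rx$modifiers)
    if (!all(touched %in% species)) {
      abort(sprintf("reaction %d references unknown species: %s", r,
                    paste(setdiff(touched, species), collapse = ", ")))
    }
    stoich[rx$substrates, r] <- stoich[rx$substrates, r] - 1L
    stoich[rx$products, r] <- stoich[rx$products, r] + 1L
    # slot columns into the species matrix, substrates first then modifiers
    reactions[[r]]$slot_idx <- match(c(rx$substrates, rx$modifiers), species)
  }
  enzymes <- unique(vapply(reactions, `[[`, character(1), "enzyme"))
  structure(
    list(id = id, species = species, reactions = reactions,
         stoich = stoich, observables = observables, enzymes = enzymes),
    class = "kinflow_network"
  )
}

#' @export
print.kinflow_network <- function(x, ...) {
  cat("<kinflow_network> ", x$id, "\n", sep = "")
  cat("  species:     ", paste(x$species, collapse = ", "), "\n", sep = "")
  for (rx in x$reactions) {
    cat(sprintf("  reaction:    %s [%s] %s -> %s%s\n", rx$enzyme, rx$law,
                paste(rx$substrates, collapse = " + "),
                paste(rx$products, collapse = " + "),
                if (length(rx$modifiers))
                  paste0(" (mod: ", paste(rx$modifiers, collapse = ", "), ")")
                else ""))
  }
  cat("  observables: ", paste(x$observables, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default parameter names required by a topology
#'
#' One entry per reaction role, named `<enzyme>_<role>`.
#' @param net A `kinflow_network` or topology id.
#' @return Character vector of parameter names.
#' @export
network_params <- function(net) {
  if (is.character(net)) net <- topology(net)
  unlist(lapply(net$reactions, function(rx) paste(rx$enzyme, rx$roles, sep = "_")),
         use.names = FALSE)
}

# ---------------------------------------------------------------------------
# topology registry

topology_registry <- new.env(parent = emptyenv())

#' Topology registry
#'
#' Built-in topologies:
#' * `"mm"`: single-substrate Michaelis-Menten conversion S -> P.
#' * `"mm_uncompetitive"`: S -> P with an unconsumed uncompetitive inhibitor I
#'   (its steady-state concentration equals its inflow concentration).
#' * `"gdh"`: glucose dehydrogenase, Glc + NAD -> GDL + NADH.
#' * `"hk"`: hexokinase, Glc + ATP -> G6P + ADP.
#' * `"gdh_hk"`: both enzymes sharing the glucose pool; only NADH observable.
#' * `"g6pdh_h0"` .. `"g6pdh_h4"`: G6P + NAD -> PGL + NADH under the five
#'   NADH-product-inhibition hypotheses.
#'
#' @param id Topology identifier.
#' @param net A `kinflow_network` to register.
#' @return `topology()` returns the `kinflow_network`; `list_topologies()` a
#'   character vector of ids.
#' @export
topology <- function(id) {
  if (!exists(id, envir = topology_registry, inherits = FALSE)) {
    abort(sprintf("Unknown topology '%s'. Known: %s.",
                  id, paste(list_topologies(), collapse = ", ")))
  }
  get(id, envir = topology_registry, inherits = FALSE)
}

#' @rdname topology
#' @export
list_topologies <- function() sort(ls(topology_registry))

#' @rdname topology
#' @export
register_topology <- function(net) {
  stopifnot(inherits(net, "kinflow_network"))
  assign(net$id, net, envir = topology_registry)
  invisible(net$id)
}

register_builtin_topologies <- function() {
  register_topology(flow_network(
    "mm", species = c("S", "P"),
    reactions = list(reaction("mm", c(S = "S"), "P", enzyme = "E")),
    observables = c("S", "P")
  ))
  register_topology(flow_network(
    "mm_uncompetitive", species = c("S", "P", "I"),
    reactions = list(reaction("mm_uncompetitive", c(S = "S"), "P",
                              modifiers = c(I = "I"), enzyme = "E")),
    observables = c("S", "P")
  ))
  register_topology(flow_network(
    "gdh", species = c("Glc", "NAD", "GDL", "NADH"),
    reactions = list(reaction("bi_mm", c(A = "Glc", B = "NAD"),
                              c("GDL", "NADH"), enzyme = "GDH")),
    observables = "NADH"
  ))
  register_topology(flow_network(
    "hk", species = c("Glc", "ATP", "G6P", "ADP"),
    reactions = list(reaction("bi_mm", c(A = "Glc", B = "ATP"),
                              c("G6P", "ADP"), enzyme = "HK")),
    observables = "ADP"
  ))
  register_topology(flow_network(
    "gdh_hk",
    species = c("Glc", "NAD", "GDL", "NADH", "ATP", "G6P", "ADP"),
    reactions = list(
      reaction("bi_mm", c(A = "Glc", B = "NAD"), c("GDL", "NADH"), enzyme = "GDH"),
      reaction("bi_mm", c(A = "Glc", B = "ATP"), c("G6P", "ADP"), enzyme = "HK")
    ),
    observables = "NADH"
  ))
  for (h in 0:4) {
    register_topology(flow_network(
      paste0("g6pdh_h", h), species = c("G6P", "NAD", "PGL", "NADH"),
      reactions = list(reaction(paste0("g6pdh_h", h),
                                c(A = "G6P", B = "NAD"), c("PGL", "NADH"),
                                modifiers = c(H = "NADH"), enzyme = "G6PDH")),
      observables = "NADH"
    ))
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_topologies()
}

# conditions helpers -------------------------------------------------------

# Extract C_in (n x species), k_f (n) and per-enzyme loading (n x enzymes)
# from a conditions data frame. Missing inflow_<sp> columns default to 0,
# missing enz_<enzyme> columns to 1.
conditions_matrices <- function(data, net) {
  n <- nrow(data)
  if (!("k_f" %in% names(data))) abort("conditions need a `k_f` column.")
  k_f <- as.numeric(data$k_f)
  assert_positive(k_f, "k_f")
  C_in <- matrix(0, n, length(net$species),
                 dimnames = list(NULL, net$species))
  for (sp in net$species) {
    col <- paste0("inflow_", sp)
    if (col %in% names(data)) {
      v <- as.numeric(data[[col]])
      v[is.na(v)] <- 0
      assert_nonnegative(v, col)
      C_in[, sp] <- v
    }
  }
  Enz <- matrix(1, n, length(net$enzymes),
                dimnames = list(NULL, net$enzymes))
  for (e in net$enzymes) {
    col <- paste0("enz_", e)
    if (col %in% names(data)) {
      v <- as.numeric(data[[col]])
      v[is.na(v)] <- 1
      assert_nonnegative(v, col)
      Enz[, e] <- v
    }
  }
  list(C_in = C_in, k_f = k_f, Enz = Enz)
}

# Build per-reaction role-value matrices (n x n_roles) from a named parameter
# vector using the default <enzyme>_<role> naming.
params_to_role_matrices <- function(net, params, n) {
  lapply(net$reactions, function(rx) {
    nm <- paste(rx$enzyme, rx$roles, sep = "_")
    missing <- setdiff(nm, names(params))
    if (length(missing)) {
      abort(sprintf("missing parameters: %s", paste(missing, collapse = ", ")))
    }
    matrix(rep(as.numeric(params[nm]), each = n), nrow = n,
           dimnames = list(NULL, rx$roles))
  })
}
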