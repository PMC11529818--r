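## Synthetic connectomes with planted modular source-to-DN structure:
## aggression-interneuron-like sources split into modules, each module
## strongly wired to its own descending-neuron (DN) pairs, one DN pair
## shared between two modules, inhibitory relays realising indirect
## source -> intermediate -> pC1d-like motifs, and a sparse Erdos-Renyi
## background layer with weights drawn around the synapse cutoff to
## exercise thresholding.

#' Script for a synthetic connectome
#'
#' @param nSourcesPerHemisphere sources of the focal class per hemisphere
#'   (default 8, mirroring the 8-9 such neurons per hemisphere).
#' @param nModules planted modules among the sources (default 3).
#' @param nDnsPerModule module-specific strong DN pairs (default 2).
#' @param sharedDn plant one DN strong to modules 1 and 2 (default TRUE).
#' @param nIntermediates relay neurons (default 6); the first is the
#'   GABAergic relay of the planted indirect inhibitory motif onto a
#'   pC1d-like node, the second a glutamatergic relay.
#' @param strongRange synapse-count range of planted strong edges
#'   (default 40-80).
#' @param backgroundRange synapse-count range of background edges (default
#'   3-12; counts below the cutoff are dropped at load time).
#' @param backgroundDensity Erdos-Renyi edge probability of the background
#'   layer (default 0.05).
#' @param synapseCutoff cutoff the consuming graph applies (default 10).
#' @param seed integer seed.
#' @return list of class `connectomeScript`.
#' @export
connectomeScript <- function(nSourcesPerHemisphere = 8, nModules = 3,
                             nDnsPerModule = 2, sharedDn = TRUE,
                             nIntermediates = 6, strongRange = c(40, 80),
                             backgroundRange = c(3, 12),
                             backgroundDensity = 0.05, synapseCutoff = 10,
                             seed = 1) {
  script <- list(nSourcesPerHemisphere = nSourcesPerHemisphere,
                 nModules = nModules, nDnsPerModule = nDnsPerModule,
                 sharedDn = sharedDn, nIntermediates = nIntermediates,
                 strongRange = strongRange, backgroundRange = backgroundRange,
                 backgroundDensity = backgroundDensity,
                 synapseCutoff = synapseCutoff, seed = seed)
  class(script) <- "connectomeScript"
  script
}

#' Generate a synthetic connectome with ground truth
#'
#' Builds the node and edge tables from the script and returns the loaded
#' [ConnectomeGraph-class] together with the planted ground truth: module
#' labels per source, the strong DN set per module, the shared DN, and the
#' analytic NT-resolved weight of each planted indirect inhibitory motif
#' (cholinergic source -> GABAergic relay -> pC1d-like node), computed in
#' closed form as \eqn{W_1 W_2/(W_1+W_2)} on the ACh-to-GABA cell.
#'
#' Neurotransmitters are assigned per presynaptic neuron: sources and the
#' pC1d-like nodes are cholinergic, designated relays GABAergic or
#' glutamatergic, DNs cholinergic; every synapse of an edge carries its
#' presynaptic neuron's NT.
#'
#' @param script a [connectomeScript()].
#' @return list with `graph`, `truth` (list: `modules`, `strongDns`,
#'   `sharedDn`, `motifs` data.frame with the analytic values), `script`.
#' @export
generateConnectome <- function(script) {
  set.seed(script$seed)
  nt0 <- stats::setNames(rep(0L, 6L), ntNames())

  src_ids <- character(0); src_hemi <- character(0)
  for (h in c("left", "right")) {
    src_ids <- c(src_ids, sprintf("cl_%s_%d", substr(h, 1, 1),
                                  seq_len(script$nSourcesPerHemisphere)))
    src_hemi <- c(src_hemi, rep(h, script$nSourcesPerHemisphere))
  }
  modules <- stats::setNames(rep_len(seq_len(script$nModules),
                                     length(src_ids)), src_ids)

  dn_ids <- unlist(lapply(seq_len(script$nModules), function(m)
    sprintf("dn_m%d_%d", m, seq_len(script$nDnsPerModule))))
  dn_module <- rep(seq_len(script$nModules), each = script$nDnsPerModule)
  if (script$sharedDn) {
    dn_ids <- c(dn_ids, "dn_shared")
    dn_module <- c(dn_module, NA_integer_)
  }
  int_ids <- sprintf("relay_%d", seq_len(script$nIntermediates))
  pc1_ids <- c("pc1d_l", "pc1d_r")

  nodes <- data.frame(
    id = c(src_ids, dn_ids, int_ids, pc1_ids),
    type = c(rep("CL062", length(src_ids)), rep("DN", length(dn_ids)),
             rep("intermediate", length(int_ids)), rep("pC1d", 2L)),
    hemisphere = c(src_hemi, rep("left/right", length(dn_ids)),
                   rep("left/right", length(int_ids)), c("left", "right")),
    stringsAsFactors = FALSE)

  ## presynaptic NT per node: relays 1/2 inhibitory, all else cholinergic
  nt_of <- stats::setNames(rep("ach", nrow(nodes)), nodes$id)
  if (script$nIntermediates >= 1L) nt_of[int_ids[1L]] <- "gaba"
  if (script$nIntermediates >= 2L) nt_of[int_ids[2L]] <- "glut"

  edges <- list()
  addEdge <- function(pre, post, count) {
    nt <- nt0
    nt[nt_of[[pre]]] <- count
    edges[[length(edges) + 1L]] <<- c(list(pre = pre, post = post,
                                           count = count), as.list(nt))
  }
  drawW <- function(rng) sample(seq(rng[1], rng[2]), 1L)

  ## planted module -> DN strong edges
  for (s in src_ids) {
    for (d in dn_ids[which(dn_module == modules[[s]])])
      addEdge(s, d, drawW(script$strongRange))
    if (script$sharedDn && modules[[s]] %in% c(1L, 2L))
      addEdge(s, "dn_shared", drawW(script$strongRange))
  }

  ## planted indirect inhibitory motifs: module-1 sources -> GABA relay ->
  ## ipsilateral pC1d-like node
  motifs <- data.frame()
  if (script$nIntermediates >= 1L) {
    relay <- int_ids[1L]
    m1 <- src_ids[modules == 1L]
    w2 <- drawW(script$strongRange)
    addEdge(relay, pc1_ids[1L], w2)
    for (s in m1) {
      w1 <- drawW(script$strongRange)
      addEdge(s, relay, w1)
      motifs <- rbind(motifs, data.frame(
        source = s, intermediate = relay, target = pc1_ids[1L],
        w1 = w1, w2 = w2, ach_to_gaba = w1 * w2 / (w1 + w2)))
    }
  }

  ## sparse background layer over ordered node pairs
  ids <- nodes$id
  existing <- vapply(edges, function(e) paste(e$pre, e$post), "")
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    if (stats::runif(1) >= script$backgroundDensity) next
    key <- paste(ids[i], ids[j])
    if (key %in% existing) next
    addEdge(ids[i], ids[j], drawW(script$backgroundRange))
  }

  edges <- do.call(rbind, lapply(edges, as.data.frame))
  graph <- connectomeGraph(edges, nodes, cutoff = script$synapseCutoff)

  strongDns <- lapply(seq_len(script$nModules), function(m) {
    d <- dn_ids[which(dn_module == m)]
    if (script$sharedDn && m %in% c(1L, 2L)) d <- c(d, "dn_shared")
    d
  })
  list(graph = graph,
       truth = list(modules = modules, strongDns = strongDns,
                    sharedDn = if (script$sharedDn) "dn_shared" else NULL,
                    motifs = motifs,
                    sources = src_ids, dns = dn_ids, pc1 = pc1_ids),
       script = script)
}

#' Write / read a connectome script as JSON
#'
#' @param script a [connectomeScript()].
#' @param path file path.
#' @return the path (writing) or a script (reading).
#' @export
writeConnectomeScript <- function(script, path) {
  jsonlite::write_json(unclass(script), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeConnectomeScript
#' @export
readConnectomeScript <- function(path) {
  do.call(connectomeScript, jsonlite::read_json(path, simplifyVector = TRUE))
}
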