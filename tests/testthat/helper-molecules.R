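# Shared fixtures: small molecules and an independent rooted-subgraph
# isomorphism oracle (igraph VF2) for signature canonicality checks.

suppressWarnings(suppressMessages({
  requireNamespace("igraph", quietly = TRUE)
}))

# Quiet OpenBabel chatter on stderr is expected; nothing here hides R
# conditions.

smi1 <- function(s) parse_smiles(s)[[1]]

# small molecules (<= 12 atoms counting hydrogens) for brute-force work
SMALL_MOLS <- c(
  "C", "CC", "CCC", "CCO", "CO", "C=C", "C#C", "C=O", "CC=O", "CCN",
  "CN", "CNC", "C#N", "CC#N", "OCO", "OCC=O", "C1CC1", "C1CCC1",
  "C1CO1", "C1CN1", "C1COC1", "C1CCO1", "c1ccccc1", "c1ccoc1",
  "c1ccsc1", "c1cc[nH]c1", "c1ccncc1", "CC(C)C", "CC(C)O", "CC(N)C",
  "CC(=O)O", "C(=O)O", "NC=O", "CC(=O)N", "COC", "CSC", "CS", "OS",
  "O=S=O", "CCl", "CBr", "CF", "CI", "C(Cl)Cl", "ClCCl", "FC(F)F",
  "C=CC", "C=CC=C", "C#CC", "CC(C)=O", "OCC(O)C", "NCC(O)C", "OCCN",
  "OCCO", "NCCN", "C1=CC1", "CC1CC1", "OC1CC1", "O", "N", "OO", "NN",
  "NO", "CCF", "OC=O", "OC=C", "NC=C", "C=C=C", "OCC#N", "SC#N",
  "ClC=C", "C1=CC=C1", "O=C1CC1", "N1CC1C", "OC(=O)C=C", "ClCC#N")

# ball of radius h around `center`: igraph + integer colours for VF2
ball_graph <- function(mg, center, h) {
  D <- npscore:::.bfs_dist(npscore:::.mg_adjacency(mg)$nb, center, h)
  ball <- which(!is.na(D) & D <= h)
  sub <- npscore:::mg_induced(mg, ball)
  layer <- D[ball]
  vcol <- paste(layer, sub$elem, sub$arom, sub$charge)
  # aromatic bonds are one bond class regardless of the Kekulé order
  ecol <- ifelse(sub$barom, "ar", as.character(sub$bonds[, 3]))
  g <- igraph::make_empty_graph(n = length(ball), directed = FALSE)
  if (nrow(sub$bonds)) g <- igraph::add_edges(g, t(sub$bonds[, 1:2]))
  list(g = g, vcol = vcol, ecol = ecol)
}

# independent oracle: are two rooted neighbourhood subgraphs isomorphic?
balls_isomorphic <- function(b1, b2) {
  if (length(b1$vcol) != length(b2$vcol)) return(FALSE)
  vlev <- sort(unique(c(b1$vcol, b2$vcol)))
  elev <- sort(unique(c(b1$ecol, b2$ecol)))
  if (!setequal(b1$vcol, b2$vcol)) return(FALSE)
  igraph::graph.isomorphic.vf2(
    b1$g, b2$g,
    vertex.color1 = match(b1$vcol, vlev),
    vertex.color2 = match(b2$vcol, vlev),
    edge.color1 = match(b1$ecol, elev),
    edge.color2 = match(b2$ecol, elev))$iso
}

# deterministic fixture corpora shared across expensive tests
fixture_dir <- function(n_np, n_sm, seed, sugar_fraction = 0.4) {
  dir <- file.path(tempdir(),
                   sprintf("fx_%d_%d_%d_%s", n_np, n_sm, seed,
                           gsub("\\.", "p", as.character(sugar_fraction))))
  if (!file.exists(file.path(dir, "np.smi")))
    generate_corpora(n_np, n_sm, seed, sugar_fraction, dir)
  list(np_file = file.path(dir, "np.smi"),
       sm_file = file.path(dir, "sm.smi"),
       key = read.delim(file.path(dir, "answer_key.tsv"), sep = "\t",
                        stringsAsFactors = FALSE))
}

# graphs of the first n molecules of a .smi file
smi_graphs <- function(path, n = Inf) {
  lines <- readLines(path)
  smiles <- vapply(strsplit(lines, " "), `[`, "", 1)
  if (is.finite(n)) smiles <- utils::head(smiles, n)
  parse_smiles(smiles)
}

sig_identical <- function(a, b) {
  identical(as.integer(a), as.integer(b)) &&
    identical(names(a), names(b))
}
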