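Package: priorityrank
Title: Priority Attachment Network Generation and Re-Creation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates directed and undirected networks with the priority
    attachment mechanism: each vertex ranks all other vertices with a
    pluggable distance function and selects edge targets with probability
    inversely proportional to rank position (normalized by a generalized
    harmonic sum). Includes a catalogue of distance-function families
    (random, centrality-based, euclidean, cosine, aggregate, hierarchical,
    disassortative, and learned regression/naive-Bayes distances), reference
    generators (Erdos-Renyi, Watts-Strogatz, Albert-Barabasi, forest fire,
    Dorogovtsev-Goltsev-Mendes, disassortative), synthetic vertex-attribute
    generation, a Kolmogorov-Smirnov network-comparison suite over centrality
    distributions, and a workflow that learns the distance function best
    re-creating a given network and emits families of similar networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
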