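Package: flyaggr
Title: Quantification of Optogenetically Evoked Aggression in Drosophila and
    Resistor-Circuit Connectome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying aggression-like actions of Drosophila
    melanogaster evoked by optogenetic stimulation, and for analysing the
    descending-neuron circuitry thought to drive them. Covers pixel-statistics
    foreground segmentation of behavioural video, direct linear transformation
    (DLT) camera calibration and 3D triangulation of tracked body parts,
    derivation of kinematic observables (wing pitch, wing offset, body
    elevation, wing elevation/azimuth, speed, wingspan), rule-based ethogram
    classification (wing threat, wing extension, low wing threat, alert
    stance) with bout and latency statistics, sliding-window Gaussian mixture
    habituation analysis, and BCa bootstrap estimation statistics. The
    connectome side implements resistor-circuit equivalent connection weights
    over direct and one-intermediate paths with neurotransmitter-resolved path
    decomposition, cosine-similarity hierarchical clustering, PCA biplots and
    SVM separating planes. Synthetic-data generators emulate multi-camera pose
    sessions with scripted action bouts and synapse graphs with planted
    modular structure, so every stage is testable without raw videos or a
    connectome download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    mclust,
    e1071,
    boot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Software, Neuroscience, Network, GraphAndNetwork, Clustering
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'actionStats.R'
    'bootstrap.R'
    'connectomeModularity.R'
    'connectomeWeights.R'
    'flyaggr-package.R'
    'framePreprocess.R'
    'gmmHabituation.R'
    'observables.R'
    'pipeline.R'
    'poseGeometry.R'
    'syntheticConnectome.R'
    'syntheticPose.R'
    'syntheticRig.R'
    'triangulation.R'
    'utils.R'
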