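format-version: 1.2
! Synthetic mini-ontology. The CCO chain GO:0043227 is_a GO:0043226 is_a
! GO:0110165 is real GO structure; the terms GO:0043229 and GO:1990900 are
! wired synthetically so that GO:0043227 and GO:1990900 are joined only
! through the common ancestor GO:0043226 by a 3-edge path (SRP 3.5), and
! GO:0044238 stands alone in a second domain (SRP +Inf from any CCO term).

[Term]
id: GO:0110165
name: cellular anatomical entity
namespace: cellular_component

[Term]
id: GO:0043226
name: organelle
namespace: cellular_component
is_a: GO:0110165 ! cellular anatomical entity

[Term]
id: GO:0043227
name: membrane-bounded organelle
namespace: cellular_component
is_a: GO:0043226 ! organelle

[Term]
id: GO:0043229
name: intracellular organelle
namespace: cellular_component
is_a: GO:0043226 ! organelle

[Term]
id: GO:1990900
name: synthetic indirect partner
namespace: cellular_component
is_a: GO:0043229 ! intracellular organelle

[Term]
id: GO:0044238
name: primary metabolic process
namespace: biological_process
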