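format-version: 1.2
ontology: venomics-mini-go
remark: synthetic miniature molecular-function subset (is_a edges only) used by the study generator and the enrichment tests

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0003824
name: catalytic activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0005488
name: binding
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0016787
name: hydrolase activity
namespace: molecular_function
is_a: GO:0003824 ! catalytic activity

[Term]
id: GO:0016740
name: transferase activity
namespace: molecular_function
is_a: GO:0003824 ! catalytic activity

[Term]
id: GO:0008233
name: peptidase activity
namespace: molecular_function
is_a: GO:0016787 ! hydrolase activity

[Term]
id: GO:0004175
name: endopeptidase activity
namespace: molecular_function
is_a: GO:0008233 ! peptidase activity

[Term]
id: GO:0004252
name: serine-type endopeptidase activity
namespace: molecular_function
is_a: GO:0004175 ! endopeptidase activity

[Term]
id: GO:0005515
name: protein binding
namespace: molecular_function
is_a: GO:0005488 ! binding

[Term]
id: GO:0003676
name: nucleic acid binding
namespace: molecular_function
is_a: GO:0005488 ! binding

[Term]
id: GO:0043167
name: ion binding
namespace: molecular_function
is_a: GO:0005488 ! binding

[Term]
id: GO:0043169
name: cation binding
namespace: molecular_function
is_a: GO:0043167 ! ion binding
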