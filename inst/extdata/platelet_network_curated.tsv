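# Curated, synthetic approximation of the platelet-aggregation signalling
# network: 64 typed nodes, 91 directed edges, single terminal event.
# Wiring assembled from public pathway knowledge (KEGG platelet activation,
# Reactome); it is a best-effort reconstruction, not an exact copy of any
# published diagram. All edges carry the default initial weight (10).
%node Collagen	Collagen	protein
%node von Willebrand factor	von Willebrand factor	protein
%node ADP	ADP	small_molecule
%node ATP	ATP	small_molecule
%node Epinephrine	Epinephrine	small_molecule
%node Thromboxane A2	Thromboxane A2	small_molecule
%node Fibrinogen	Fibrinogen	protein
%node GPVI	Glycoprotein VI	protein
%node FcR gamma-chain	Fc receptor gamma-chain	protein
%node GPIb-IX-V	Glycoprotein Ib-IX-V complex	protein
%node Integrin alpha2/beta1	Integrin alpha2/beta1	protein
%node P2Y purinoceptor 1	P2Y purinoceptor 1	protein
%node P2Y purinoceptor 12	P2Y purinoceptor 12	protein
%node P2X purinoceptor 1	P2X purinoceptor 1	protein
%node Proteinase-activated receptor 1	Proteinase-activated receptor 1	protein
%node Proteinase-activated receptor 4	Proteinase-activated receptor 4	protein
%node Thromboxane A2 receptor alpha	Thromboxane A2 receptor alpha	protein
%node Thromboxane A2 receptor beta	Thromboxane A2 receptor beta	protein
%node Alpha-2A adrenergic receptor	Alpha-2A adrenergic receptor	protein
%node Lyn	Tyrosine-protein kinase Lyn	protein
%node Fyn	Tyrosine-protein kinase Fyn	protein
%node Syk	Tyrosine-protein kinase Syk	protein
%node LAT	Linker for activation of T cells	protein
%node SLP-76	Lymphocyte cytosolic protein 2	protein
%node Btk	Bruton tyrosine kinase	protein
%node Gq	G protein subunit alpha q	protein
%node Gi	G protein subunit alpha i	protein
%node G12/13	G protein subunit alpha 12/13	protein
%node Gs	G protein subunit alpha s	protein
%node Phosphoinositide phospholipase C beta-2	Phosphoinositide phospholipase C beta-2	protein
%node Phosphoinositide phospholipase C gamma-2	Phosphoinositide phospholipase C gamma-2	protein
%node phosphatidylinositol 3-kinase	Phosphatidylinositol 3-kinase	protein
%node RAC-alpha serine/threonine-protein kinase	RAC-alpha serine/threonine-protein kinase	protein
%node Protein kinase C	Protein kinase C	protein
%node Phospholipase A2	Phospholipase A2	protein
%node Prostaglandin G/H synthase 1	Prostaglandin G/H synthase 1	protein
%node Adenylate cyclase	Adenylate cyclase	protein
%node Thrombin	Thrombin	protein
%node Inositol 1,4,5-trisphosphate receptor	Inositol 1,4,5-trisphosphate receptor	protein
%node Ras-related protein	Ras-related protein Rap-1b	protein
%node Glycoprotein IIb/IIIa complex	Glycoprotein IIb/IIIa complex	protein
%node Thromboxane-A synthase	Thromboxane-A synthase	protein
%node Protein kinase A	cAMP-dependent protein kinase	protein
%node CalDAG-GEFI	Calcium and DAG-regulated GEF I	protein
%node RIAM	Rap1-GTP-interacting adaptor molecule	protein
%node Talin	Talin-1	protein
%node Kindlin-3	Kindlin-3	protein
%node Rho	Transforming protein RhoA	protein
%node ROCK	Rho-associated protein kinase	protein
%node Myosin light chain kinase	Myosin light chain kinase	protein
%node Myosin light chain	Myosin regulatory light chain	protein
%node Calmodulin	Calmodulin	protein
%node PIP2	Phosphatidylinositol 4,5-bisphosphate	small_molecule
%node PIP3	Phosphatidylinositol 3,4,5-trisphosphate	small_molecule
%node IP3	Inositol 1,4,5-trisphosphate	small_molecule
%node DAG	Diacylglycerol	small_molecule
%node Calcium	Cytosolic calcium	small_molecule
%node cAMP	Cyclic AMP	small_molecule
%node Arachidonic acid	Arachidonic acid	small_molecule
%node Prostaglandin H2	Prostaglandin H2	small_molecule
%node Shape change	Platelet shape change	event
%node Dense granule secretion	Dense granule secretion	event
%node Alpha granule secretion	Alpha granule secretion	event
%node Platelet aggregation	Platelet aggregation	event
%exit Platelet aggregation
Collagen	GPVI
Collagen	Integrin alpha2/beta1
von Willebrand factor	GPIb-IX-V
GPVI	FcR gamma-chain
GPVI	Fyn
FcR gamma-chain	Syk
Lyn	Syk
Fyn	Syk
Syk	LAT
LAT	SLP-76
LAT	phosphatidylinositol 3-kinase
SLP-76	Btk
SLP-76	Phosphoinositide phospholipase C gamma-2
Btk	Phosphoinositide phospholipase C gamma-2
GPIb-IX-V	Lyn
GPIb-IX-V	phosphatidylinositol 3-kinase
ADP	P2Y purinoceptor 1
ADP	P2Y purinoceptor 12
ATP	P2X purinoceptor 1
P2Y purinoceptor 1	Gq
P2Y purinoceptor 12	Gi
P2X purinoceptor 1	Calcium
Thrombin	Proteinase-activated receptor 1
Thrombin	Proteinase-activated receptor 4
Thrombin	GPIb-IX-V
Proteinase-activated receptor 1	Gq
Proteinase-activated receptor 1	G12/13
Proteinase-activated receptor 4	Gq
Proteinase-activated receptor 4	G12/13
Thromboxane A2	Thromboxane A2 receptor alpha
Thromboxane A2	Thromboxane A2 receptor beta
Thromboxane A2 receptor alpha	Gq
Thromboxane A2 receptor alpha	G12/13
Thromboxane A2 receptor beta	Gq
Thromboxane A2 receptor beta	G12/13
Epinephrine	Alpha-2A adrenergic receptor
Alpha-2A adrenergic receptor	Gi
Gq	Phosphoinositide phospholipase C beta-2
Gi	phosphatidylinositol 3-kinase
Gi	Adenylate cyclase
Gs	Adenylate cyclase
G12/13	Rho
PIP2	Phosphoinositide phospholipase C beta-2
PIP2	Phosphoinositide phospholipase C gamma-2
PIP2	phosphatidylinositol 3-kinase
Phosphoinositide phospholipase C beta-2	IP3
Phosphoinositide phospholipase C beta-2	DAG
Phosphoinositide phospholipase C gamma-2	IP3
Phosphoinositide phospholipase C gamma-2	DAG
phosphatidylinositol 3-kinase	PIP3
PIP3	RAC-alpha serine/threonine-protein kinase
PIP3	Btk
IP3	Inositol 1,4,5-trisphosphate receptor
Inositol 1,4,5-trisphosphate receptor	Calcium
Calcium	Protein kinase C
DAG	Protein kinase C
Calcium	Phospholipase A2
Calcium	CalDAG-GEFI
DAG	CalDAG-GEFI
Calcium	Calmodulin
Calmodulin	Myosin light chain kinase
Myosin light chain kinase	Myosin light chain
Myosin light chain	Shape change
Shape change	Platelet aggregation
Rho	ROCK
ROCK	Myosin light chain
Phospholipase A2	Arachidonic acid
Arachidonic acid	Prostaglandin G/H synthase 1
Prostaglandin G/H synthase 1	Prostaglandin H2
Prostaglandin H2	Thromboxane-A synthase
Thromboxane-A synthase	Thromboxane A2
Adenylate cyclase	cAMP
cAMP	Protein kinase A
Protein kinase A	Ras-related protein
Protein kinase C	Dense granule secretion
Protein kinase C	Alpha granule secretion
Calcium	Dense granule secretion
RAC-alpha serine/threonine-protein kinase	Dense granule secretion
Dense granule secretion	ADP
Dense granule secretion	ATP
Alpha granule secretion	Fibrinogen
Alpha granule secretion	von Willebrand factor
CalDAG-GEFI	Ras-related protein
Ras-related protein	RIAM
RIAM	Talin
Talin	Glycoprotein IIb/IIIa complex
Kindlin-3	Glycoprotein IIb/IIIa complex
Protein kinase C	Glycoprotein IIb/IIIa complex
Fibrinogen	Glycoprotein IIb/IIIa complex
Glycoprotein IIb/IIIa complex	Platelet aggregation
Integrin alpha2/beta1	Platelet aggregation
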