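node_id	parent_id	rank	name
1	1	root	root
B	1	kingdom	Bacteria
B_p1	B	phylum	Bacteria phylum 1
B_p1_c1	B_p1	class	Bacteria class 1.1
B_p1_c1_g1	B_p1_c1	genus	Bacteria genus 1.1.1
B_p1_c1_g2	B_p1_c1	genus	Bacteria genus 1.1.2
B_p1_c1_g3	B_p1_c1	genus	Bacteria genus 1.1.3
B_p1_c2	B_p1	class	Bacteria class 1.2
B_p1_c2_g1	B_p1_c2	genus	Bacteria genus 1.2.1
B_p1_c2_g2	B_p1_c2	genus	Bacteria genus 1.2.2
B_p1_c2_g3	B_p1_c2	genus	Bacteria genus 1.2.3
B_p2	B	phylum	Bacteria phylum 2
B_p2_c1	B_p2	class	Bacteria class 2.1
B_p2_c1_g1	B_p2_c1	genus	Bacteria genus 2.1.1
B_p2_c1_g2	B_p2_c1	genus	Bacteria genus 2.1.2
B_p2_c1_g3	B_p2_c1	genus	Bacteria genus 2.1.3
B_p2_c2	B_p2	class	Bacteria class 2.2
B_p2_c2_g1	B_p2_c2	genus	Bacteria genus 2.2.1
B_p2_c2_g2	B_p2_c2	genus	Bacteria genus 2.2.2
B_p2_c2_g3	B_p2_c2	genus	Bacteria genus 2.2.3
B_p3	B	phylum	Bacteria phylum 3
B_p3_c1	B_p3	class	Bacteria class 3.1
B_p3_c1_g1	B_p3_c1	genus	Bacteria genus 3.1.1
B_p3_c1_g2	B_p3_c1	genus	Bacteria genus 3.1.2
B_p3_c1_g3	B_p3_c1	genus	Bacteria genus 3.1.3
B_p3_c2	B_p3	class	Bacteria class 3.2
B_p3_c2_g1	B_p3_c2	genus	Bacteria genus 3.2.1
B_p3_c2_g2	B_p3_c2	genus	Bacteria genus 3.2.2
B_p3_c2_g3	B_p3_c2	genus	Bacteria genus 3.2.3
E	1	kingdom	Eukaryota
E_p1	E	phylum	Eukaryota phylum 1
E_p1_c1	E_p1	class	Eukaryota class 1.1
E_p1_c1_g1	E_p1_c1	genus	Eukaryota genus 1.1.1
E_p1_c1_g2	E_p1_c1	genus	Eukaryota genus 1.1.2
E_p1_c1_g3	E_p1_c1	genus	Eukaryota genus 1.1.3
E_p1_c2	E_p1	class	Eukaryota class 1.2
E_p1_c2_g1	E_p1_c2	genus	Eukaryota genus 1.2.1
E_p1_c2_g2	E_p1_c2	genus	Eukaryota genus 1.2.2
E_p1_c2_g3	E_p1_c2	genus	Eukaryota genus 1.2.3
E_p2	E	phylum	Eukaryota phylum 2
E_p2_c1	E_p2	class	Eukaryota class 2.1
E_p2_c1_g1	E_p2_c1	genus	Eukaryota genus 2.1.1
E_p2_c1_g2	E_p2_c1	genus	Eukaryota genus 2.1.2
E_p2_c1_g3	E_p2_c1	genus	Eukaryota genus 2.1.3
E_p2_c2	E_p2	class	Eukaryota class 2.2
E_p2_c2_g1	E_p2_c2	genus	Eukaryota genus 2.2.1
E_p2_c2_g2	E_p2_c2	genus	Eukaryota genus 2.2.2
E_p2_c2_g3	E_p2_c2	genus	Eukaryota genus 2.2.3
E_p3	E	phylum	Eukaryota phylum 3
E_p3_c1	E_p3	class	Eukaryota class 3.1
E_p3_c1_g1	E_p3_c1	genus	Eukaryota genus 3.1.1
E_p3_c1_g2	E_p3_c1	genus	Eukaryota genus 3.1.2
E_p3_c1_g3	E_p3_c1	genus	Eukaryota genus 3.1.3
E_p3_c2	E_p3	class	Eukaryota class 3.2
E_p3_c2_g1	E_p3_c2	genus	Eukaryota genus 3.2.1
E_p3_c2_g2	E_p3_c2	genus	Eukaryota genus 3.2.2
E_p3_c2_g3	E_p3_c2	genus	Eukaryota genus 3.2.3
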