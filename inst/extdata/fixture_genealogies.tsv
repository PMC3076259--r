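name	newick	max_exclusive	pooled_exclusive
ancient_block_13	(((((((((((((a1|ancient,a2|ancient),a3|ancient),a4|ancient),a5|ancient),a6|ancient),a7|ancient),a8|ancient),a9|ancient),a10|ancient),a11|ancient),a12|ancient),a13|ancient),(m1|modern,(m2|modern,m3|modern)));	13	13
alternating	((a1|ancient,m1|modern),(a2|ancient,m2|modern));	1	0
two_cherries	(((a1|ancient,a2|ancient),m1|modern),((a3|ancient,a4|ancient),m2|modern));	2	4
nested_mixed	((((a1|ancient,a2|ancient),a3|ancient),(m1|modern,m2|modern)),((a4|ancient,m3|modern),a5|ancient));	3	3
random12_01	((t1|modern:0.396,(t2|ancient:0.019,(t3|ancient:0.909,t4|modern:0.82):0.506):0.723):0.986,(t5|modern:0.849,(t6|modern:0.219,((t7|modern:0.429,(t8|ancient:0.862,(t9|ancient:0.555,t10|modern:0.905):0.784):0.91):0.874,(t11|modern:0.911,t12|ancient:0.29):0.312):0.443):0.825):0.885);	1	0
random12_02	((t1|modern:0.298,((t2|modern:0.971,t3|modern:0.96):0.543,t4|ancient:0.726):0.933):0.765,((t5|modern:0.383,t6|ancient:0.418):0.404,(t7|ancient:0.078,(t8|modern:0.054,(t9|ancient:0.35,(t10|modern:0.665,(t11|modern:0.944,t12|modern:0.76):0.124):0.586):0.331):0.145):0.341):0.84);	1	0
random12_03	(((((t1|ancient:0.946,t2|modern:0.452):0.84,t3|ancient:0.175):0.99,((t4|modern:0.068,t5|modern:0.859):0.949,t6|ancient:0.459):0.699):0.023,(t7|modern:0.812,t8|modern:0.868):0.002):0.035,((t9|modern:0.896,t10|modern:0.05):0.924,(t11|ancient:0.869,t12|ancient:0.63):0.697):0.04);	2	2
random12_04	(((t1|modern:0.938,(t2|modern:0.907,((t3|modern:0.601,t4|ancient:0.813):0.338,t5|ancient:0.688):0.558):0.066):0.186,(t6|modern:0.941,((t7|ancient:0.478,t8|ancient:0.469):0.385,t9|modern:0.313):0.674):0.399):0.282,((t10|modern:0.839,t11|modern:0.578):0.538,t12|modern:0.665):0.153);	2	2
random12_05	(((t1|modern:0.923,(t2|modern:0.097,(t3|ancient:0.189,((t4|modern:0.44,t5|modern:0.637):0.84,t6|modern:0.995):0.036):0.244):0.637):0.492,(t7|modern:0.272,(t8|modern:0.292,(t9|modern:0.202,t10|modern:0.211):0.228):0.483):0.937):0.285,(t11|modern:0.556,t12|modern:0.5):0.724);	1	0
random12_06	(t1|modern:0.572,(((t2|ancient:0.732,t3|modern:0.812):0.924,((t4|ancient:0.643,(t5|ancient:0.794,t6|ancient:0.632):0.678):0.118,t7|ancient:0.595):0.572):0.658,(t8|modern:0.883,(t9|ancient:0.34,(t10|modern:0.457,(t11|modern:0.156,t12|modern:0.099):0.963):0.636):0.163):0.499):0.189);	4	4
random12_07	(((t1|modern:0.24,t2|modern:0.776):0.091,(t3|modern:0.728,((t4|modern:0.066,(t5|ancient:0.458,t6|modern:0.8):0.15):0.396,(t7|modern:0.214,t8|modern:0.73):0.754):0.143):0.676):0.723,(t9|modern:0.183,(t10|ancient:0.789,(t11|modern:0.476,t12|ancient:0.182):0.976):0.388):0.608);	1	0
random12_08	(((t1|ancient:0.049,t2|modern:0.534):0.719,(t3|ancient:0.744,t4|ancient:0.421):0.389):0.804,(((t5|ancient:0.559,t6|ancient:0.399):0.732,t7|ancient:0.716):0.63,((t8|ancient:0.666,t9|modern:0.112):0.364,(t10|ancient:0.302,(t11|ancient:0.048,t12|ancient:0.917):0.983):0.248):0.32):0.41);	3	8
random12_09	((((t1|ancient:0.17,(t2|modern:0.63,t3|ancient:0.922):0.649):0.161,((t4|ancient:0.441,t5|modern:0.122):0.49,(t6|ancient:0.886,t7|modern:0.203):0.286):0.496):0.632,(t8|ancient:0.774,(t9|ancient:0.371,t10|ancient:0.037):0.33):0.439):0.358,(t11|modern:0.775,t12|modern:0.51):0.112);	3	3
random12_10	(t1|modern:0.566,((t2|modern:0.544,(t3|modern:0.582,t4|modern:0.512):0.845):0.597,((t5|modern:0.573,(t6|modern:0.577,(t7|ancient:0.935,(t8|modern:0.328,t9|modern:0.363):0.206):0.435):0.899):0.134,(t10|ancient:0.938,(t11|ancient:0.205,t12|modern:0.435):0.647):0.6):0.907):0.511);	1	0
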