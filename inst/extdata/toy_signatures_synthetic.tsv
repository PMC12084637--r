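Type	SYN_FLAT	SYN_CPG	SYN_CLOCK	SYN_TCC
A[C>A]A	0.01104	0.001121	0.004221	0.002899
A[C>A]C	0.005375	0.001121	0.010162	0.002899
A[C>A]G	0.027071	0.001121	0.005004	0.002899
A[C>A]T	0.016181	0.001121	0.011966	0.002899
C[C>A]A	0.006431	0.001121	0.012584	0.002899
C[C>A]C	0.006016	0.001121	0.00496	0.002899
C[C>A]G	0.00801	0.001121	0.01591	0.002899
C[C>A]T	0.020404	0.001121	0.008472	0.002899
G[C>A]A	0.027574	0.001121	0.006938	0.002899
G[C>A]C	0.006004	0.001121	0.012059	0.002899
G[C>A]G	0.005285	0.001121	0.008411	0.002899
G[C>A]T	0.007376	0.001121	0.007817	0.002899
T[C>A]A	0.012102	0.001121	0.011179	0.002899
T[C>A]C	0.013473	0.001121	0.007766	0.002899
T[C>A]G	0.003779	0.001121	0.006233	0.002899
T[C>A]T	0.014525	0.001121	0.013972	0.002899
A[C>G]A	0.003629	0.001121	0.009531	0.002899
A[C>G]C	0.020265	0.001121	0.009894	0.002899
A[C>G]G	0.001963	0.001121	0.007869	0.002899
A[C>G]T	0.014404	0.001121	0.013863	0.002899
C[C>G]A	0.007213	0.001121	0.017606	0.002899
C[C>G]C	0.009943	0.001121	0.006932	0.002899
C[C>G]G	0.004719	0.001121	0.005991	0.002899
C[C>G]T	0.004274	0.001121	0.002881	0.002899
G[C>G]A	0.013535	0.001121	0.014893	0.002899
G[C>G]C	0.005612	0.001121	0.004631	0.002899
G[C>G]G	0.005587	0.001121	0.013043	0.002899
G[C>G]T	0.000912	0.001121	0.003372	0.002899
T[C>G]A	0.008103	0.001121	0.016783	0.002899
T[C>G]C	0.011444	0.001121	0.003851	0.002899
T[C>G]G	0.00907	0.001121	0.007952	0.002899
T[C>G]T	0.003986	0.001121	0.009971	0.002899
A[C>T]A	0.006668	0.001121	0.014971	0.002899
A[C>T]C	0.013352	0.001121	0.01809	0.002899
A[C>T]G	0.030139	0.224215	0.005986	0.002899
A[C>T]T	0.00201	0.001121	0.009412	0.002899
C[C>T]A	0.00081	0.001121	0.010232	0.002899
C[C>T]C	0.008639	0.001121	0.012309	0.002899
C[C>T]G	0.002795	0.224215	0.014581	0.002899
C[C>T]T	0.005049	0.001121	0.003303	0.002899
G[C>T]A	0.007715	0.001121	0.005687	0.002899
G[C>T]C	0.015553	0.001121	0.015205	0.002899
G[C>T]G	0.0075	0.224215	0.004108	0.002899
G[C>T]T	0.005827	0.001121	0.008435	0.002899
T[C>T]A	0.003194	0.001121	0.01636	0.002899
T[C>T]C	0.011941	0.001121	0.019231	0.724638
T[C>T]G	0.022951	0.224215	0.002006	0.002899
T[C>T]T	0.010912	0.001121	0.006406	0.002899
A[T>A]A	0.002285	0.001121	0.004727	0.002899
A[T>A]C	0.012887	0.001121	0.007282	0.002899
A[T>A]G	0.008431	0.001121	0.00495	0.002899
A[T>A]T	0.012563	0.001121	0.007505	0.002899
C[T>A]A	0.015618	0.001121	0.00344	0.002899
C[T>A]C	0.011563	0.001121	0.004979	0.002899
C[T>A]G	0.009309	0.001121	0.014797	0.002899
C[T>A]T	0.005191	0.001121	0.030638	0.002899
G[T>A]A	0.01256	0.001121	0.006717	0.002899
G[T>A]C	0.005345	0.001121	0.00789	0.002899
G[T>A]G	0.007123	0.001121	0.015113	0.002899
G[T>A]T	0.004664	0.001121	0.019624	0.002899
T[T>A]A	0.009907	0.001121	0.011222	0.002899
T[T>A]C	0.002682	0.001121	0.019632	0.002899
T[T>A]G	0.015225	0.001121	0.010829	0.002899
T[T>A]T	0.008562	0.001121	0.00705	0.002899
A[T>C]A	0.012114	0.001121	0.007485	0.002899
A[T>C]C	0.005175	0.001121	0.023117	0.002899
A[T>C]G	0.013754	0.001121	0.006888	0.002899
A[T>C]T	0.019655	0.001121	0.007471	0.002899
C[T>C]A	0.020564	0.001121	0.015392	0.002899
C[T>C]C	0.004705	0.001121	0.02181	0.002899
C[T>C]G	0.025916	0.001121	0.025846	0.002899
C[T>C]T	0.024547	0.001121	0.007664	0.002899
G[T>C]A	0.008883	0.001121	0.017812	0.002899
G[T>C]C	0.013445	0.001121	0.003775	0.002899
G[T>C]G	0.004402	0.001121	0.007961	0.002899
G[T>C]T	0.006792	0.001121	0.006435	0.002899
T[T>C]A	0.019202	0.001121	0.005331	0.002899
T[T>C]C	0.008494	0.001121	0.005891	0.002899
T[T>C]G	0.01576	0.001121	0.009244	0.002899
T[T>C]T	0.022083	0.001121	0.008136	0.002899
A[T>G]A	0.011888	0.001121	0.01028	0.002899
A[T>G]C	0.00484	0.001121	0.016307	0.002899
A[T>G]G	0.008076	0.001121	0.018129	0.002899
A[T>G]T	0.010743	0.001121	0.009244	0.002899
C[T>G]A	0.022666	0.001121	0.013544	0.002899
C[T>G]C	0.009157	0.001121	0.004558	0.002899
C[T>G]G	0.003534	0.001121	0.017642	0.002899
C[T>G]T	0.020335	0.001121	0.011634	0.002899
G[T>G]A	0.006381	0.001121	0.007497	0.002899
G[T>G]C	0.014253	0.001121	0.010934	0.002899
G[T>G]G	0.006794	0.001121	0.012362	0.002899
G[T>G]T	0.006633	0.001121	0.01229	0.002899
T[T>G]A	0.001713	0.001121	0.004453	0.002899
T[T>G]C	0.007524	0.001121	0.009205	0.002899
T[T>G]G	0.011119	0.001121	0.011749	0.002899
T[T>G]T	0.014576	0.001121	0.010481	0.002899
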