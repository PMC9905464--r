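radius_mm,energy_fraction_per_mm3
5.000e-02,4.172908562e-03
1.500e-01,3.987477176e-03
2.500e-01,3.810285797e-03
3.500e-01,3.640968265e-03
4.500e-01,3.479174691e-03
5.500e-01,3.324570731e-03
6.500e-01,3.176836902e-03
7.500e-01,3.035667916e-03
8.500e-01,2.900772051e-03
9.500e-01,2.771870548e-03
1.050e+00,2.648697037e-03
1.150e+00,2.530996983e-03
1.250e+00,2.418527162e-03
1.350e+00,2.311055158e-03
1.450e+00,2.208358884e-03
1.550e+00,2.110226120e-03
1.650e+00,2.016454079e-03
1.750e+00,1.926848982e-03
1.850e+00,1.841225664e-03
1.950e+00,1.759407186e-03
2.050e+00,1.681224472e-03
2.150e+00,1.606515961e-03
2.250e+00,1.535127270e-03
2.350e+00,1.466910875e-03
2.450e+00,1.401725810e-03
2.550e+00,1.339437371e-03
2.650e+00,1.279916841e-03
2.750e+00,1.223041223e-03
2.850e+00,1.168692984e-03
2.950e+00,1.116759816e-03
3.050e+00,1.067134401e-03
3.150e+00,1.019714188e-03
3.250e+00,9.744011859e-04
3.350e+00,9.311017558e-04
3.450e+00,8.897264208e-04
3.550e+00,8.501896801e-04
3.650e+00,8.124098321e-04
3.750e+00,7.763088059e-04
3.850e+00,7.418119996e-04
3.950e+00,7.088481267e-04
4.050e+00,6.773490682e-04
4.150e+00,6.472497322e-04
4.250e+00,6.184879194e-04
4.350e+00,5.910041941e-04
4.450e+00,5.647417622e-04
4.550e+00,5.396463530e-04
4.650e+00,5.156661076e-04
4.750e+00,4.927514714e-04
4.850e+00,4.708550922e-04
4.950e+00,4.499317215e-04
5.050e+00,4.299381219e-04
5.150e+00,4.108329772e-04
5.250e+00,3.925768071e-04
5.350e+00,3.751318858e-04
5.450e+00,3.584621638e-04
5.550e+00,3.425331936e-04
5.650e+00,3.273120585e-04
5.750e+00,3.127673044e-04
5.850e+00,2.988688751e-04
5.950e+00,2.855880497e-04
6.050e+00,2.728973839e-04
6.150e+00,2.607706527e-04
6.250e+00,2.491827967e-04
6.350e+00,2.381098698e-04
6.450e+00,2.275289901e-04
6.550e+00,2.174182927e-04
6.650e+00,2.077568839e-04
6.750e+00,1.985247988e-04
6.850e+00,1.897029595e-04
6.950e+00,1.812731360e-04
7.050e+00,1.732179082e-04
7.150e+00,1.655206303e-04
7.250e+00,1.581653960e-04
7.350e+00,1.511370061e-04
7.450e+00,1.444209364e-04
7.550e+00,1.380033085e-04
7.650e+00,1.318708605e-04
7.750e+00,1.260109198e-04
7.850e+00,1.204113772e-04
7.950e+00,1.150606612e-04
8.050e+00,1.099477147e-04
8.150e+00,1.050619721e-04
8.250e+00,1.003933371e-04
8.350e+00,9.593216200e-05
8.450e+00,9.166922800e-05
8.550e+00,8.759572584e-05
8.650e+00,8.370323775e-05
8.750e+00,7.998372001e-05
8.850e+00,7.642948634e-05
8.950e+00,7.303319203e-05
9.050e+00,6.978781872e-05
9.150e+00,6.668665995e-05
9.250e+00,6.372330726e-05
9.350e+00,6.089163697e-05
9.450e+00,5.818579751e-05
9.550e+00,5.560019733e-05
9.650e+00,5.312949338e-05
9.750e+00,5.076858001e-05
9.850e+00,4.851257846e-05
9.950e+00,4.635682677e-05
1.005e+01,4.429687014e-05
1.015e+01,4.232845173e-05
1.025e+01,4.044750386e-05
1.035e+01,3.865013959e-05
1.045e+01,3.693264474e-05
1.055e+01,3.529147015e-05
1.065e+01,3.372322437e-05
1.075e+01,3.222466667e-05
1.085e+01,3.079270033e-05
1.095e+01,2.942436622e-05
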